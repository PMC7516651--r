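#' Specification of a synthetic MR-like phantom
#'
#' Describes a 2-D phantom emulating the essential structure of a
#' T2-weighted scan: bright elliptical "anatomy" composited over a dark
#' background, optionally blurred, with magnitude-image noise added on top.
#' Rendering is fully deterministic; all randomness lives in the noise
#' stage, keyed by `seed`, so identical spec + seed gives a bit-identical
#' image.
#'
#' The default geometry is a body-sized ellipse with a brighter fluid-like
#' core carrying a mild intensity gradient and a small hypointense lesion,
#' on a near-black background -- the bright-tissue / dark-noise-floor
#' composition typical of clinical T2w slices.
#'
#' @param height,width canvas size in pixels.
#' @param background_level background intensity (integer).
#' @param structures list of ellipses, each a list with `center` (row, col),
#'   `axes` (semi-axes in pixels), `angle` (degrees, counter-clockwise),
#'   `intensity`, and optional `gradient` (signed fraction of `intensity`
#'   ramped along the major axis; 0 = flat).
#' @param noise_model `"none"`, `"gaussian"`, or `"rician"` (the magnitude
#'   of a complex signal under i.i.d. Gaussian channel noise -- the MR
#'   magnitude-image noise model; Rayleigh in the background).
#' @param sigma noise scale in intensity units.
#' @param blur_sigma optional Gaussian blur scale in pixels (applied to the
#'   clean render, before noise); `NULL` = no blur.  Requires EBImage.
#' @param seed integer seed for the noise stage.
#' @param bit_depth 8 or 16; intensities are clipped to `[0, 2^bit_depth - 1]`.
#' @return Object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec(sigma = 10, seed = 42)
#' img <- render_phantom(spec)
#' @export
phantom_spec <- function(height = 128, width = 128, background_level = 8,
                         structures = default_structures(height, width),
                         noise_model = c("rician", "gaussian", "none"),
                         sigma = 0, blur_sigma = NULL, seed = 0,
                         bit_depth = 8) {
  noise_model <- match.arg(noise_model)
  stopifnot(height >= 3, width >= 3, sigma >= 0, bit_depth %in% c(8, 16))
  structure(
    list(height = as.integer(height), width = as.integer(width),
         background_level = background_level, structures = structures,
         noise_model = noise_model, sigma = sigma, blur_sigma = blur_sigma,
         seed = as.integer(seed), bit_depth = as.integer(bit_depth)),
    class = "phantom_spec")
}

default_structures <- function(height, width) {
  cy <- height / 2; cx <- width / 2
  list(
    list(center = c(cy, cx), axes = c(0.40 * height, 0.32 * width),
         angle = 15, intensity = 140, gradient = 0),
    list(center = c(cy - 0.05 * height, cx), axes = c(0.22 * height, 0.16 * width),
         angle = 15, intensity = 220, gradient = -0.25),
    list(center = c(cy + 0.18 * height, cx - 0.10 * width),
         axes = c(0.06 * height, 0.05 * width), angle = 0,
         intensity = 60, gradient = 0))
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %d x %d, %d structure(s), noise %s (sigma %g), seed %d, %d-bit\n",
    x$height, x$width, length(x$structures), x$noise_model, x$sigma,
    x$seed, x$bit_depth))
  invisible(x)
}

#' Render the clean (noise-free) phantom image
#'
#' Deterministic rasterization: structures are painted in list order over
#' the uniform background, later structures overwriting earlier ones.  A
#' structure whose bounding box leaves the canvas is clipped with a
#' warning.  No randomness is consumed.
#'
#' @param spec a [phantom_spec()].
#' @return A [grayscale_image()] carrying a `bit_depth` attribute.
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  img <- matrix(spec$background_level, spec$height, spec$width)
  rows <- matrix(seq_len(spec$height), spec$height, spec$width)
  cols <- matrix(seq_len(spec$width), spec$height, spec$width, byrow = TRUE)
  for (st in spec$structures) {
    theta <- st$angle * pi / 180
    dy <- rows - st$center[1]
    dx <- cols - st$center[2]
    u <- dy * cos(theta) + dx * sin(theta)    # along the first (major) axis
    v <- -dy * sin(theta) + dx * cos(theta)
    inside <- (u / st$axes[1])^2 + (v / st$axes[2])^2 <= 1
    if (st$center[1] - st$axes[1] < 1 || st$center[1] + st$axes[1] > spec$height ||
        st$center[2] - st$axes[2] < 1 || st$center[2] + st$axes[2] > spec$width) {
      warning("structure extends outside the canvas; clipped", call. = FALSE)
    }
    grad <- if (is.null(st$gradient)) 0 else st$gradient
    val <- st$intensity * (1 + grad * (u / st$axes[1]) / 2)
    img[inside] <- val[inside]
  }
  if (!is.null(spec$blur_sigma) && spec$blur_sigma > 0) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("blur_sigma requires the EBImage package", call. = FALSE)
    }
    img <- EBImage::gblur(img, sigma = spec$blur_sigma)
  }
  maxval <- 2^spec$bit_depth - 1
  img <- round(pmin(pmax(img, 0), maxval))
  out <- grayscale_image(img, source_id = sprintf(
    "phantom_%dx%d_clean", spec$height, spec$width))
  attr(out, "bit_depth") <- spec$bit_depth
  out
}

#' Add simulated acquisition noise to an image
#'
#' `"gaussian"` adds i.i.d. zero-mean Gaussian noise to intensities;
#' `"rician"` models MR magnitude images, replacing each true intensity A
#' by `sqrt((A + n1)^2 + n2^2)` with independent `n1, n2 ~ N(0, sigma)` --
#' non-negative by construction and Rayleigh-distributed where A = 0.
#' Output is rounded and clipped to the image's bit-depth range.  Seeding is
#' scoped: the caller's RNG state is untouched.
#'
#' @param image a [grayscale_image()].
#' @param model `"none"`, `"gaussian"`, or `"rician"`.
#' @param sigma noise scale in intensity units (>= 0).
#' @param seed integer seed.
#' @param bit_depth clipping range; defaults to the image's `bit_depth`
#'   attribute, else 8.
#' @return A [grayscale_image()] of the same size.
#' @export
add_noise <- function(image, model = c("rician", "gaussian", "none"),
                      sigma, seed = 0, bit_depth = NULL) {
  image <- as_image(image)
  model <- match.arg(model)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (is.null(bit_depth)) {
    bit_depth <- attr(image, "bit_depth")
    if (is.null(bit_depth)) bit_depth <- 8L
  }
  if (model == "none" || (model == "gaussian" && sigma == 0)) return(image)
  px <- pixels(image)
  noisy <- withr::with_seed(as.integer(seed), {
    n <- length(px)
    switch(model,
      gaussian = px + stats::rnorm(n, sd = sigma),
      rician = sqrt((px + stats::rnorm(n, sd = sigma))^2 +
                    stats::rnorm(n, sd = sigma)^2))
  })
  maxval <- 2^bit_depth - 1
  noisy <- round(pmin(pmax(noisy, 0), maxval))
  dim(noisy) <- dim(px)
  out <- grayscale_image(noisy, source_id = sprintf(
    "%s+%s(sigma=%g,seed=%d)", attr(image, "source_id"), model, sigma, seed))
  attr(out, "bit_depth") <- as.integer(bit_depth)
  out
}

#' Render a graded-distortion series from one phantom geometry
#'
#' Renders the clean image once and adds independently seeded noise at each
#' requested level, producing a severity-graded image set for sensitivity
#' studies.
#'
#' @param spec a [phantom_spec()]; its `noise_model` is used at every level
#'   (a level of `sigma = 0` returns the clean render).
#' @param sigmas numeric vector of noise scales.
#' @param seeds integer vector, one per level; defaults to
#'   `spec$seed + 0:(length(sigmas)-1)`.
#' @return A list with one element per level: `list(sigma =, image =)`.
#' @examples
#' series <- graded_series(phantom_spec(), sigmas = c(5, 40), seeds = c(1, 2))
#' vapply(series, function(s) enmiqa(s$image)$value, numeric(1))
#' @export
graded_series <- function(spec, sigmas, seeds = NULL) {
  stopifnot(inherits(spec, "phantom_spec"), length(sigmas) >= 1)
  if (is.null(seeds)) seeds <- spec$seed + seq_along(sigmas) - 1L
  stopifnot(length(seeds) == length(sigmas))
  clean <- render_phantom(spec)
  Map(function(sg, sd) {
    img <- if (sg == 0) clean else {
      add_noise(clean, model = spec$noise_model, sigma = sg, seed = sd)
    }
    list(sigma = sg, image = img)
  }, sigmas, seeds)
}
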