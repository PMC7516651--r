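#' Grayscale image container
#'
#' Wraps a 2-D matrix of non-negative integer intensities together with a
#' provenance label.  This is the object every scoring function consumes:
#' rows index image height (M), columns width (N), and intensities are kept
#' in the native integer units of the source format (no silent rescaling),
#' because the extrema thresholds are defined in those units.
#'
#' @param pixels numeric matrix of non-negative integers, at least 3 x 3.
#' @param source_id free-text provenance label (file name, phantom spec, ...).
#' @return An object of class `grayscale_image`: the pixel matrix with
#'   attribute `source_id`.
#' @examples
#' img <- grayscale_image(matrix(0:24, 5, 5), source_id = "ramp")
#' dim(img)
#' @export
grayscale_image <- function(pixels, source_id = "image") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 3L || ncol(pixels) < 3L) {
    stop("image must be at least 3 x 3; got ", nrow(pixels), " x ",
         ncol(pixels), call. = FALSE)
  }
  if (anyNA(pixels)) stop("image contains missing values", call. = FALSE)
  if (any(pixels < 0)) stop("intensities must be non-negative", call. = FALSE)
  if (any(pixels != round(pixels))) {
    stop("intensities must be integers; round or rescale explicitly",
         call. = FALSE)
  }
  storage.mode(pixels) <- "double"  # doubles hold 16-bit ranges exactly
  attributes(pixels) <- list(dim = dim(pixels))  # drop decoder metadata
  structure(pixels,
            source_id = as.character(source_id)[1],
            class = c("grayscale_image", "matrix", "array"))
}

#' @export
print.grayscale_image <- function(x, ...) {
  cat(sprintf("<grayscale_image> %d x %d, intensities [%g, %g], id: %s\n",
              nrow(x), ncol(x), min(x), max(x), attr(x, "source_id")))
  invisible(x)
}

#' Test whether an object is a grayscale image
#' @param x object to test.
#' @return `TRUE` for objects created by [grayscale_image()].
#' @export
is_grayscale_image <- function(x) inherits(x, "grayscale_image")

#' Extract the bare pixel matrix of an image
#' @param image a [grayscale_image()].
#' @return A plain numeric matrix without class or provenance attributes.
#' @export
pixels <- function(image) {
  x <- unclass(image)
  attributes(x) <- list(dim = dim(x))
  x
}

as_image <- function(x, source_id = "image") {
  if (is_grayscale_image(x)) x else grayscale_image(x, source_id)
}

#' Pixel neighborhood for non-maximum suppression
#'
#' The suppression test compares a pixel against either its 4 axial
#' neighbors or its full 8-pixel 3 x 3 neighborhood.  The full neighborhood
#' is the default: with only 4 neighbors, diagonal impulses escape
#' suppression and the measure discriminates quality visibly worse.
#'
#' @param size 4 or 8.
#' @return An object of class `nms_neighborhood`: an integer matrix of
#'   (row offset, column offset) pairs with a `size` attribute.
#' @examples
#' neighborhood(4)
#' @export
neighborhood <- function(size = 8) {
  size <- as.integer(size)
  if (!size %in% c(4L, 8L)) {
    stop("neighborhood size must be 4 or 8, got ", size, call. = FALSE)
  }
  off <- if (size == 4L) {
    rbind(c(0L, 1L), c(0L, -1L), c(1L, 0L), c(-1L, 0L))
  } else {
    as.matrix(expand.grid(i = -1:1, j = -1:1))[-5L, , drop = FALSE]
  }
  dimnames(off) <- list(NULL, c("i", "j"))
  structure(off, size = size, class = c("nms_neighborhood", "matrix", "array"))
}

#' @export
print.nms_neighborhood <- function(x, ...) {
  cat(sprintf("<nms_neighborhood> size %d\n", attr(x, "size")))
  invisible(x)
}

as_neighborhood <- function(x) {
  if (inherits(x, "nms_neighborhood")) x else neighborhood(x)
}
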