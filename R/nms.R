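#' Thresholded non-maximum suppression test at one pixel
#'
#' A pixel passes the test at threshold `t` when it is strictly greater than
#' every neighbor plus `t`, or strictly less than every neighbor minus `t`.
#' Plateaus (equal-valued neighbors) never pass: both branches are strict.
#' The test is only defined for interior pixels, i.e. pixels whose whole
#' neighborhood lies inside the image; the 1-pixel border is never tested.
#'
#' @param image a [grayscale_image()] (or a plain integer matrix).
#' @param row,col 1-based pixel coordinates; must be interior.
#' @param t intensity threshold, integer >= 1.
#' @param nbhd a [neighborhood()] or 4/8.
#' @return 1 if the pixel is a thresholded local extremum, 0 otherwise.
#' @examples
#' img <- grayscale_image(matrix(c(0, 0, 0, 0, 100, 0, 0, 0, 0), 3, 3))
#' nms_test(img, 2, 2, t = 50)
#' @export
nms_test <- function(image, row, col, t, nbhd = neighborhood(8)) {
  image <- as_image(image)
  nbhd <- as_neighborhood(nbhd)
  if (t < 1) stop("threshold t must be >= 1", call. = FALSE)
  m <- nrow(image); n <- ncol(image)
  if (row < 2 || row > m - 1) {
    stop("row ", row, " is not interior for a ", m, "-row image", call. = FALSE)
  }
  if (col < 2 || col > n - 1) {
    stop("col ", col, " is not interior for a ", n, "-column image",
         call. = FALSE)
  }
  center <- image[row, col]
  nb <- image[cbind(row + nbhd[, "i"], col + nbhd[, "j"])]
  as.integer(all(center > nb + t) || all(center < nb - t))
}

# Signed extremum margins for all interior pixels, computed once per image:
# up[a,b] = I(a,b) - max(neighbors), dn[a,b] = min(neighbors) - I(a,b).
# The pixel passes the test at threshold t iff up > t or dn > t (mutually
# exclusive), so the whole profile falls out of two matrices.
extrema_margins <- function(image, nbhd) {
  m <- nrow(image); n <- ncol(image)
  center <- image[2:(m - 1), 2:(n - 1), drop = FALSE]
  nb_max <- nb_min <- NULL
  for (k in seq_len(nrow(nbhd))) {
    shifted <- image[(2 + nbhd[k, "i"]):(m - 1 + nbhd[k, "i"]),
                     (2 + nbhd[k, "j"]):(n - 1 + nbhd[k, "j"]), drop = FALSE]
    nb_max <- if (is.null(nb_max)) shifted else pmax(nb_max, shifted)
    nb_min <- if (is.null(nb_min)) shifted else pmin(nb_min, shifted)
  }
  list(up = center - nb_max, dn = nb_min - center)
}

#' Count thresholded local extrema in an image
#'
#' Sums the non-maximum suppression test over all interior pixels of the
#' image: the number of pixels strictly exceeding all neighbors by more than
#' `t`, plus the number strictly below all neighbors by more than `t`.
#'
#' @inheritParams nms_test
#' @return Non-negative integer count.
#' @examples
#' cb <- grayscale_image(255 * outer(1:8, 1:8, function(a, b) (a + b) %% 2))
#' count_extrema(cb, t = 10, nbhd = 4)  # every interior pixel
#' count_extrema(cb, t = 10, nbhd = 8)  # diagonal ties suppress all
#' @export
count_extrema <- function(image, t, nbhd = neighborhood(8)) {
  image <- as_image(image)
  nbhd <- as_neighborhood(nbhd)
  if (t < 1) stop("threshold t must be >= 1", call. = FALSE)
  mg <- extrema_margins(image, nbhd)
  sum(mg$up > t) + sum(mg$dn > t)
}

#' Extrema-count profile over a threshold sequence
#'
#' Runs the thresholded suppression for every t in 1..S and collects the
#' counts I(t).  The profile is non-increasing in t (an extremum at
#' threshold t is an extremum at every smaller threshold) and is also
#' returned normalized by the image size M*N.
#'
#' @inheritParams nms_test
#' @param S largest threshold; the sequence is the consecutive integers 1..S.
#' @return An object of class `extrema_profile` with fields `counts`
#'   (length-S integer vector), `normalized` (`counts / (M*N)`), `S`,
#'   `image_size`, `neighborhood_size` and `source_id`.
#' @examples
#' img <- grayscale_image(matrix(sample.int(256, 400, TRUE) - 1, 20, 20))
#' extrema_profile(img, S = 10)
#' @export
extrema_profile <- function(image, S = 30, nbhd = neighborhood(8)) {
  image <- as_image(image)
  nbhd <- as_neighborhood(nbhd)
  S <- as.integer(S)
  if (is.na(S) || S < 1L) stop("S must be a positive integer", call. = FALSE)
  mg <- extrema_margins(image, nbhd)
  counts <- vapply(seq_len(S),
                   function(t) sum(mg$up > t) + sum(mg$dn > t),
                   integer(1))
  size <- nrow(image) * ncol(image)
  structure(
    list(counts = counts,
         normalized = counts / size,
         S = S,
         image_size = size,
         neighborhood_size = attr(nbhd, "size"),
         source_id = attr(image, "source_id")),
    class = "extrema_profile")
}

#' @export
print.extrema_profile <- function(x, ...) {
  cat(sprintf("<extrema_profile> S = %d, nbhd %d, image size %d (%s)\n",
              x$S, x$neighborhood_size, x$image_size, x$source_id))
  cat("counts:", paste(utils::head(x$counts, 12), collapse = " "),
      if (x$S > 12) "...\n" else "\n")
  invisible(x)
}
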