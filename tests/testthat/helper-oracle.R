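# Independent brute-force oracle: a literal triple loop over interior
# pixels applying the strict two-branch suppression test.  Deliberately
# naive and separate from the package's vectorized path.
brute_force_count <- function(px, t, size = 8) {
  offsets <- if (size == 4) {
    list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))
  } else {
    ln <- list()
    for (i in -1:1) for (j in -1:1) if (i != 0 || j != 0) {
      ln[[length(ln) + 1]] <- c(i, j)
    }
    ln
  }
  m <- nrow(px); n <- ncol(px)
  total <- 0L
  for (a in 2:(m - 1)) {
    for (b in 2:(n - 1)) {
      up <- TRUE; dn <- TRUE
      for (off in offsets) {
        nb <- px[a + off[1], b + off[2]]
        if (!(px[a, b] > nb + t)) up <- FALSE
        if (!(px[a, b] < nb - t)) dn <- FALSE
      }
      if (up || dn) total <- total + 1L
    }
  }
  total
}

random_image <- function(m, n, maxval = 255) {
  grayscale_image(matrix(sample.int(maxval + 1, m * n, replace = TRUE) - 1,
                         m, n))
}

test_phantom <- function(sigma = 0, seed = 0, height = 96, width = 96, ...) {
  sp <- phantom_spec(height = height, width = width, sigma = sigma,
                     seed = seed, ...)
  img <- render_phantom(sp)
  if (sigma > 0) img <- add_noise(img, "rician", sigma, seed = seed)
  img
}
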