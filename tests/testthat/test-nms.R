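test_that("the per-pixel suppression test follows the strict two-branch rule", {
  peak <- grayscale_image(matrix(c(0, 0, 0, 0, 100, 0, 0, 0, 0), 3, 3))
  expect_identical(nms_test(peak, 2, 2, t = 50), 1L)
  expect_identical(nms_test(peak, 2, 2, t = 99), 1L)
  expect_identical(nms_test(peak, 2, 2, t = 100), 0L)

  flat <- grayscale_image(matrix(7, 5, 5))
  for (t in c(1, 5, 200)) expect_identical(nms_test(flat, 3, 3, t), 0L)

  # boundary of the strict inequality: center 10, neighbors 0
  small <- grayscale_image(matrix(c(0, 0, 0, 0, 10, 0, 0, 0, 0), 3, 3))
  expect_identical(nms_test(small, 2, 2, t = 10), 0L)
  expect_identical(nms_test(small, 2, 2, t = 9), 1L)

  # minima branch: dark pixel in bright surround
  pit <- grayscale_image(matrix(c(50, 50, 50, 50, 3, 50, 50, 50, 50), 3, 3))
  expect_identical(nms_test(pit, 2, 2, t = 46), 1L)
  expect_identical(nms_test(pit, 2, 2, t = 47), 0L)

  expect_error(nms_test(peak, 1, 2, t = 1), "row")
  expect_error(nms_test(peak, 2, 3, t = 1), "col")
})

test_that("count_extrema matches the brute-force double sum on random images", {
  set.seed(101)
  for (rep in 1:25) {
    m <- sample(3:16, 1); n <- sample(3:16, 1)
    img <- random_image(m, n)
    for (size in c(4, 8)) {
      nb <- neighborhood(size)
      for (t in c(1, 5, 10, 30)) {
        expect_identical(count_extrema(img, t, nb),
                         brute_force_count(img, t, size))
      }
    }
  }
})

test_that("checkerboard images separate the 4- and 8-neighborhoods", {
  for (dims in list(c(8, 8), c(9, 13))) {
    cb <- grayscale_image(
      255 * outer(seq_len(dims[1]), seq_len(dims[2]),
                  function(a, b) (a + b) %% 2))
    for (t in c(1, 100, 254)) {
      expect_equal(count_extrema(cb, t, neighborhood(4)),
                   (dims[1] - 2) * (dims[2] - 2))
      expect_equal(count_extrema(cb, t, neighborhood(8)), 0)
    }
  }
})

test_that("extrema profiles are non-increasing, prefix-stable and bounded", {
  set.seed(202)
  for (rep in 1:20) {
    img <- random_image(sample(5:24, 1), sample(5:24, 1))
    for (size in c(4, 8)) {
      pr <- extrema_profile(img, S = 30, nbhd = neighborhood(size))
      expect_length(pr$counts, 30)
      expect_true(all(diff(pr$counts) <= 0))
      expect_true(all(pr$counts >= 0 & pr$counts <= pr$image_size))
      expect_identical(pr$normalized, pr$counts / pr$image_size)
      # prefix property: thresholds are independent of S
      pr10 <- extrema_profile(img, S = 10, nbhd = neighborhood(size))
      expect_identical(pr$counts[1:10], pr10$counts)
    }
  }
})

test_that("profile matches the per-threshold brute-force oracle on a noisy phantom", {
  img <- test_phantom(sigma = 20, seed = 7, height = 32, width = 32)
  pr <- extrema_profile(img, S = 30)
  oracle <- vapply(1:30, function(t) brute_force_count(img, t, 8), integer(1))
  expect_identical(pr$counts, oracle)
})

test_that("counts are invariant to intensity shifts and image complement", {
  set.seed(303)
  for (rep in 1:10) {
    img <- random_image(10, 12, maxval = 200)
    base <- extrema_profile(img, S = 20)$counts
    shifted <- grayscale_image(unclass(img) + 37)
    expect_identical(extrema_profile(shifted, S = 20)$counts, base)
    flipped <- grayscale_image(max(img) - unclass(img))
    expect_identical(extrema_profile(flipped, S = 20)$counts, base)
  }
})

test_that("the 8-neighborhood profile is transpose-equivariant", {
  set.seed(404)
  for (rep in 1:10) {
    img <- random_image(9, 14)
    expect_identical(extrema_profile(grayscale_image(t(unclass(img))), S = 15)$counts,
                     extrema_profile(img, S = 15)$counts)
  }
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(grayscale_image(matrix(0, 2, 5)), "at least 3 x 3")
  expect_error(grayscale_image(matrix(-1, 3, 3)), "non-negative")
  expect_error(grayscale_image(matrix(0.5, 3, 3)), "integers")
  expect_error(neighborhood(6), "4 or 8")
  img <- grayscale_image(matrix(0, 4, 4))
  expect_error(count_extrema(img, t = 0), "threshold")
  expect_error(extrema_profile(img, S = 0), "positive integer")
})
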