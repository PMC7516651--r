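test_that("clean rendering is deterministic and places structures correctly", {
  sp <- phantom_spec(height = 64, width = 64, background_level = 10,
                     structures = list(list(center = c(32, 32),
                                            axes = c(20, 14), angle = 0,
                                            intensity = 200, gradient = 0)))
  img1 <- render_phantom(sp)
  img2 <- render_phantom(sp)
  expect_identical(pixels(img1), pixels(img2))
  expect_equal(img1[32, 32], 200)
  expect_equal(img1[1, 1], 10)

  empty <- phantom_spec(height = 32, width = 32, background_level = 5,
                        structures = list())
  expect_true(all(render_phantom(empty) == 5))

  overflow <- phantom_spec(height = 32, width = 32, structures = list(
    list(center = c(2, 2), axes = c(10, 10), angle = 0, intensity = 99,
         gradient = 0)))
  expect_warning(render_phantom(overflow), "clipped")
})

test_that("intensity gradients ramp along the major axis and stay in range", {
  sp <- phantom_spec(height = 64, width = 64, structures = list(
    list(center = c(32, 32), axes = c(24, 16), angle = 0, intensity = 100,
         gradient = 0.5)))
  img <- render_phantom(sp)
  expect_gt(img[50, 32], img[14, 32])  # ramp increases with row offset
  expect_true(all(img >= 0 & img <= 255))
})

test_that("noise injection is seeded, bounded and model-checked", {
  clean <- render_phantom(phantom_spec(height = 48, width = 48))
  expect_identical(pixels(add_noise(clean, "gaussian", 0, seed = 1)),
                   pixels(clean))
  expect_identical(pixels(add_noise(clean, "none", 10, seed = 1)),
                   pixels(clean))
  n1 <- add_noise(clean, "rician", 15, seed = 1)
  n1b <- add_noise(clean, "rician", 15, seed = 1)
  n2 <- add_noise(clean, "rician", 15, seed = 2)
  expect_identical(pixels(n1), pixels(n1b))
  expect_false(identical(pixels(n1), pixels(n2)))
  expect_true(all(n1 >= 0 & n1 <= 255))
  expect_error(add_noise(clean, "salt", 5, seed = 1))
})

test_that("rician noise at zero signal matches the Rayleigh closed forms", {
  zero <- grayscale_image(matrix(0, 256, 256))
  sigma <- 10
  noisy <- add_noise(zero, "rician", sigma, seed = 9, bit_depth = 16)
  expect_equal(mean(noisy), sigma * sqrt(pi / 2), tolerance = 0.02)
  expect_equal(var(as.numeric(noisy)), (2 - pi / 2) * sigma^2,
               tolerance = 0.03)
})

test_that("graded series shares one geometry and seeds each level independently", {
  sp <- phantom_spec(height = 48, width = 48, sigma = 0, seed = 100)
  series <- graded_series(sp, sigmas = c(0, 5, 40))
  expect_length(series, 3)
  expect_equal(vapply(series, `[[`, numeric(1), "sigma"), c(0, 5, 40))
  expect_identical(pixels(series[[1]]$image),
                   pixels(render_phantom(sp)))
  scores <- vapply(series, function(s) enmiqa(s$image)$value, numeric(1))
  expect_gt(scores[3], scores[2])  # sigma 40 scores above sigma 5
})
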