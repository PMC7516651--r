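test_that("correlation and error criteria reproduce hand-worked values", {
  expect_equal(plcc(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_equal(srcc(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_equal(krcc(c(1, 2, 3, 4), c(1, 3, 2, 4)), 4 / 6)
  expect_equal(rmse(c(1, 2), c(2, 4)), sqrt(5 / 2))

  mos <- c(2.1, 3.3, 1.2, 4.8, 2.9)
  expect_equal(plcc(mos, mos), 1)
  expect_equal(plcc(-2 * mos + 1, mos), -1)
  expect_equal(srcc(mos, mos), 1)
  expect_equal(srcc(rev(sort(mos)), sort(mos)), -1)
  expect_equal(krcc(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(rmse(mos, mos), 0)
  expect_equal(rmse(c(2, 1, 2, 1), c(1, 2, 1, 2)), 1)
})

test_that("criteria validate their inputs", {
  expect_error(plcc(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(srcc(1, 1), "at least 2")
  expect_error(krcc(2, 5), "at least 2")
  expect_error(rmse(c(1, 2), c(1, 2, 3)), "mismatch")
})

test_that("rank criteria agree with their independent formulations", {
  set.seed(31)
  for (rep in 1:100) {
    m <- sample(5:40, 1)
    Q <- rnorm(m); mos <- rnorm(m)  # continuous, tie-free a.s.
    expect_equal(srcc(Q, mos), cor(rank(Q), rank(mos)), tolerance = 1e-12)
    expect_equal(krcc(Q, mos), cor(Q, mos, method = "kendall"),
                 tolerance = 1e-12)
  }
})

test_that("ties are handled by average ranks (SRCC) and tau-a (KRCC)", {
  Q <- c(1, 2, 2, 3)
  mos <- c(1, 2, 3, 4)
  expect_equal(srcc(Q, mos), cor(rank(Q), rank(mos)))
  # 6 pairs: the (2,2) pair is tied in Q and counts toward neither
  expect_equal(krcc(Q, mos), (5 - 0) / 6)
})

test_that("rank criteria are invariant to monotone re-parameterization", {
  set.seed(32)
  Q <- rnorm(25); mos <- rnorm(25)
  expect_equal(srcc(exp(Q), mos), srcc(Q, mos), tolerance = 1e-12)
  expect_equal(krcc(Q^3, mos), krcc(Q, mos), tolerance = 1e-12)
})

test_that("the logistic mapping absorbs identity and sign flips exactly", {
  mos <- c(1.2, 2.4, 3.1, 3.9, 4.4, 2.8, 1.9, 4.9)
  fit_id <- fit_logistic(mos, mos)
  expect_lt(fit_id$rmse, 1e-8)
  fit_neg <- fit_logistic(-mos, mos)
  expect_lt(fit_neg$rmse, 1e-8)
  expect_error(fit_logistic(rep(2, 8), mos), "constant")
  expect_error(fit_logistic(mos[1:4], mos[1:4]), "at least 6")
})

test_that("the fit never does worse than the nested linear regression", {
  set.seed(33)
  for (rep in 1:10) {
    Q <- runif(30, 0, 10)
    mos <- pmin(5, pmax(1, 3 + rnorm(30)))
    # near-uncorrelated data can leave the sigmoid wandering on a flat
    # plateau until the iteration cap; the guarantee under test still holds
    fit <- suppressWarnings(fit_logistic(Q, mos))
    lin_rmse <- sqrt(mean(lm(mos ~ Q)$residuals^2))
    expect_lte(fit$rmse, lin_rmse + 1e-10)
  }
})

test_that("the fitted mapping recovers a known sigmoid relation", {
  set.seed(77)
  Q <- runif(50, 0.5, 5.5)
  truth <- 2 / (1 + exp(-1.5 * (Q - 3))) + 1
  mos <- truth + rnorm(50, sd = 0.05)
  fit <- fit_logistic(Q, mos)
  expect_equal(plcc(fit$fitted, mos), plcc(truth, mos), tolerance = 0.02)
  # predict() applies the same mapping
  expect_equal(predict(fit, Q), fit$fitted)
})

test_that("evaluate_iqa assembles the full report", {
  set.seed(41)
  Q <- runif(40, 1, 4)
  mos <- pmin(5, pmax(1, 1 + Q + rnorm(40, sd = 0.3)))
  rep <- evaluate_iqa(Q, mos, ids = sprintf("img%02d", 1:40))
  expect_s3_class(rep, "iqa_evaluation")
  expect_true(abs(rep$plcc) <= 1 && abs(rep$srcc) <= 1 && abs(rep$krcc) <= 1)
  expect_gte(rep$rmse, 0)
  expect_length(rep$beta, 5)
  expect_length(rep$residuals, 40)
  expect_s3_class(rep$jb, "jb_test")
  expect_error(evaluate_iqa(Q, mos, ids = rep("a", 40)), "duplicated")
})
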