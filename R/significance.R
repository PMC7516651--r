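#' Jarque-Bera test of normality
#'
#' Moment-based normality screen for mapping residuals:
#' `JB = n/6 * (skewness^2 + (kurtosis - 3)^2 / 4)` with sample (biased,
#' method-of-moments) skewness and kurtosis.  Asymptotically JB is
#' chi-squared with 2 degrees of freedom under normality, but convergence is
#' slow; for small samples the 5% critical value is obtained by Monte Carlo
#' simulation under the null (cached per sample size, internally seeded so
#' the decision is reproducible and the caller's RNG stream is untouched).
#'
#' @param x numeric vector, length >= 8, non-constant.
#' @param alpha significance level of the decision (default 0.05).
#' @param method `"auto"` (Monte Carlo below n = 2000, asymptotic above),
#'   `"asymptotic"`, or `"monte-carlo"`.
#' @param reps Monte Carlo replicates for the critical value.
#' @return Object of class `jb_test`: list with `statistic`, `critical`,
#'   `reject` (TRUE = normality rejected at `alpha`), `n`, `method`.
#' @examples
#' jarque_bera(rnorm(200))
#' @export
jarque_bera <- function(x, alpha = 0.05,
                        method = c("auto", "asymptotic", "monte-carlo"),
                        reps = 10000) {
  method <- match.arg(method)
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8) stop("need at least 8 observations", call. = FALSE)
  if (anyNA(x)) stop("input contains NA", call. = FALSE)
  if (stats::sd(x) == 0) stop("input is constant", call. = FALSE)
  stat <- jb_statistic(x)
  if (method == "auto") method <- if (n < 2000) "monte-carlo" else "asymptotic"
  critical <- if (method == "asymptotic") {
    stats::qchisq(1 - alpha, df = 2)
  } else {
    jb_critical(n, alpha, reps)
  }
  structure(list(statistic = stat, critical = critical,
                 reject = stat > critical, n = n, alpha = alpha,
                 method = method),
            class = "jb_test")
}

#' @export
print.jb_test <- function(x, ...) {
  cat(sprintf(
    "Jarque-Bera: JB = %.4f, %s critical value %.4f (n = %d, alpha = %g)\n",
    x$statistic, x$method, x$critical, x$n, x$alpha))
  cat(if (x$reject) "normality rejected\n" else "normality retained\n")
  invisible(x)
}

jb_statistic <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  m2 <- mean(xc^2)
  skew <- mean(xc^3) / m2^1.5
  kurt <- mean(xc^4) / m2^2
  n / 6 * (skew^2 + (kurt - 3)^2 / 4)
}

# Monte-Carlo 1-alpha quantile of JB under the null, cached per (n, alpha,
# reps).  Chunked so memory stays modest for large n; fixed internal seed.
.jb_cache <- new.env(parent = emptyenv())

jb_critical <- function(n, alpha = 0.05, reps = 10000) {
  key <- paste(n, alpha, reps, sep = "_")
  hit <- .jb_cache[[key]]
  if (!is.null(hit)) return(hit)
  stats_null <- withr::with_seed(220220, {
    chunk <- max(1L, min(reps, floor(5e6 / n)))
    out <- numeric(0)
    while (length(out) < reps) {
      k <- min(chunk, reps - length(out))
      xs <- matrix(stats::rnorm(n * k), nrow = n)
      mu <- colMeans(xs)
      xc <- sweep(xs, 2, mu)
      m2 <- colMeans(xc^2)
      skew <- colMeans(xc^3) / m2^1.5
      kurt <- colMeans(xc^4) / m2^2
      out <- c(out, n / 6 * (skew^2 + (kurt - 3)^2 / 4))
    }
    out
  })
  crit <- unname(stats::quantile(stats_null, 1 - alpha, type = 8))
  .jb_cache[[key]] <- crit
  crit
}

#' Residual-resampling variance-ratio (F) test between two quality measures
#'
#' Compares the prediction-error spread of two measures: a normal
#' distribution is fitted to each residual vector (sample mean and standard
#' deviation), `n_draws` samples are drawn from each fitted distribution,
#' and the F statistic is the ratio of the two resampled sample variances,
#' referred to the F distribution with `(n_draws - 1, n_draws - 1)` degrees
#' of freedom at the 95% confidence level.  Both the two-sided decision
#' (different variances) and the one-sided decision (A's variance smaller
#' than B's) are reported.
#'
#' The F test presumes Gaussian residuals, so by default both inputs must
#' first pass the Jarque-Bera screen at 5%; set `check_normality = FALSE`
#' only when normality is known by construction.  Note the reference
#' distribution accounts for the resampling stage only: uncertainty in the
#' fitted variances themselves is not propagated, so with short residual
#' vectors the test is anti-conservative.
#'
#' @param residuals_a,residuals_b numeric residual vectors (length >= 8).
#' @param n_draws samples drawn from each fitted normal (default 1000).
#' @param seed integer seed for the resampling stage (default 0); applied in
#'   a scoped way, the caller's RNG state is restored.
#' @param alpha significance level (default 0.05).
#' @param check_normality gate both inputs through [jarque_bera()] first.
#' @return Object of class `variance_ratio_test`: list with `ratio`
#'   (var(A draws)/var(B draws)), `df`, `p_two_sided`, `p_one_sided`
#'   (A smaller), `reject_two_sided`, `reject_one_sided`, `seed`, `n_draws`.
#' @examples
#' set.seed(3)
#' a <- rnorm(100); b <- rnorm(100, sd = 2)
#' residual_f_test(a, b, seed = 1)
#' @export
residual_f_test <- function(residuals_a, residuals_b, n_draws = 1000,
                            seed = 0, alpha = 0.05, check_normality = TRUE) {
  residuals_a <- as.numeric(residuals_a)
  residuals_b <- as.numeric(residuals_b)
  if (n_draws < 2) stop("n_draws must be >= 2", call. = FALSE)
  if (check_normality) {
    for (side in list(A = residuals_a, B = residuals_b)) {
      jb <- jarque_bera(side)
      if (jb$reject) {
        stop("residuals fail the Jarque-Bera normality screen (JB = ",
             sprintf("%.3f", jb$statistic),
             "); the variance-ratio F test is not licensed", call. = FALSE)
      }
    }
  }
  draws <- withr::with_seed(as.integer(seed), {
    da <- stats::rnorm(n_draws, mean(residuals_a), stats::sd(residuals_a))
    db <- stats::rnorm(n_draws, mean(residuals_b), stats::sd(residuals_b))
    list(a = da, b = db)
  })
  ratio <- stats::var(draws$a) / stats::var(draws$b)
  df <- c(n_draws - 1, n_draws - 1)
  p_lower <- stats::pf(ratio, df[1], df[2])
  p_two <- 2 * min(p_lower, 1 - p_lower)
  structure(
    list(ratio = ratio, df = df,
         p_two_sided = p_two,
         p_one_sided = p_lower,          # small ratio: A's variance smaller
         reject_two_sided = p_two < alpha,
         reject_one_sided = p_lower < alpha,
         alpha = alpha, seed = seed, n_draws = n_draws),
    class = "variance_ratio_test")
}

#' @export
print.variance_ratio_test <- function(x, ...) {
  cat(sprintf(
    "Variance-ratio F test: ratio = %.4f, F(%d, %d), seed %d\n",
    x$ratio, x$df[1], x$df[2], x$seed))
  cat(sprintf("  two-sided p = %.4g (%s at %g)\n", x$p_two_sided,
              if (x$reject_two_sided) "different variances" else "indistinguishable",
              x$alpha))
  cat(sprintf("  one-sided p = %.4g (A smaller: %s)\n", x$p_one_sided,
              if (x$reject_one_sided) "yes" else "not established"))
  invisible(x)
}
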