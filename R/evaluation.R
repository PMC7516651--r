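#' Five-parameter logistic mapping between objective scores and MOS
#'
#' Fits the standard IQA regression model
#' `Qp = b1 * (1/2 - 1/(1 + exp(b2 * (Q - b3)))) + b4 * Q + b5`
#' by nonlinear least squares (Levenberg-Marquardt), minimizing the sum of
#' squared residuals `Qp - MOS`.  The mapping absorbs any monotone
#' nonlinearity and the polarity of the objective score before Pearson
#' correlation and RMSE are computed; rank criteria do not need it.
#'
#' Initialization: `b1 = max(MOS) - min(MOS)`, `b2 = 1/sd(Q)`,
#' `b3 = mean(Q)`, `b4 = 0`, `b5 = mean(MOS)`, so the sigmoid starts active
#' over the data range.  Because the linear family (`b1 = 0`) is nested in
#' the model, the returned fit is never worse than the ordinary linear
#' regression of MOS on Q: if the nonlinear iteration ends above that
#' baseline it is replaced by it.
#'
#' @param Q numeric vector of objective scores, length >= 6, non-constant.
#' @param mos numeric vector of mean opinion scores, same length.
#' @param max_iter,tol Levenberg-Marquardt iteration cap (the optimizer
#'   itself caps at 1023) and convergence tolerance on the residual sum of
#'   squares.
#' @return An object of class `logistic_mapping`: list with `beta` (named
#'   length-5 vector), `fitted`, `residuals`, `rmse`, `converged`, `niter`.
#'   `converged = FALSE` flags an iteration-capped fit; the returned
#'   parameters are still the best found and are never worse than the
#'   nested linear regression.  An error is raised only when the optimizer
#'   fails outright (improper inputs or non-finite parameters).
#' @examples
#' set.seed(1)
#' Q <- runif(40, 1, 5)
#' mos <- 2 / (1 + exp(-1.5 * (Q - 3))) + 1.5 + rnorm(40, sd = 0.05)
#' fit <- fit_logistic(Q, mos)
#' fit$rmse
#' @export
fit_logistic <- function(Q, mos, max_iter = 2000, tol = 1e-8) {
  stopifnot(length(Q) == length(mos))
  if (length(Q) < 6) {
    stop("need at least 6 score pairs to fit the 5-parameter mapping",
         call. = FALSE)
  }
  if (anyNA(Q) || anyNA(mos)) stop("scores contain NA", call. = FALSE)
  if (stats::sd(Q) == 0) {
    stop("objective scores are constant; the mapping is degenerate",
         call. = FALSE)
  }
  start <- c(b1 = max(mos) - min(mos), b2 = 1 / stats::sd(Q),
             b3 = mean(Q), b4 = 0, b5 = mean(mos))
  resid_fn <- function(b) logistic5(Q, b) - mos
  fit <- withCallingHandlers(
    minpack.lm::nls.lm(
      par = start, fn = resid_fn,
      control = minpack.lm::nls.lm.control(
        maxiter = min(max_iter, 1023L), ftol = tol, ptol = tol,
        maxfev = 10L * max_iter)),
    warning = function(w) {
      if (grepl("lmdif", conditionMessage(w))) {
        invokeRestart("muffleWarning")  # reported via `converged` below
      }
    })
  beta <- fit$par
  if (fit$info == 0 || any(!is.finite(unlist(beta)))) {
    stop("logistic fit failed (info = ", fit$info, ", ", fit$message,
         ") after ", fit$niter, " iterations", call. = FALSE)
  }
  converged <- fit$info %in% c(1:4, 6, 7)
  if (!converged) {
    warning("logistic fit reached the iteration cap after ", fit$niter,
            " iterations; returning the best parameters found",
            call. = FALSE)
  }
  # nested linear baseline: never report a fit worse than lm(mos ~ Q)
  lin <- stats::lm.fit(cbind(1, Q), mos)
  beta_lin <- c(b1 = 0, b2 = start[["b2"]], b3 = start[["b3"]],
                b4 = lin$coefficients[2], b5 = lin$coefficients[1])
  if (sum(resid_fn(beta_lin)^2) < sum(resid_fn(beta)^2)) beta <- beta_lin
  fitted <- logistic5(Q, beta)
  res <- fitted - mos
  structure(
    list(beta = beta, fitted = fitted, residuals = res,
         rmse = sqrt(mean(res^2)),
         converged = converged, niter = fit$niter),
    class = "logistic_mapping")
}

logistic5 <- function(Q, b) {
  b[[1]] * (0.5 - 1 / (1 + exp(b[[2]] * (Q - b[[3]])))) + b[[4]] * Q + b[[5]]
}

#' @export
print.logistic_mapping <- function(x, ...) {
  cat("<logistic_mapping> beta:",
      paste(sprintf("%.4g", x$beta), collapse = ", "),
      sprintf("| RMSE %.4f (%d iterations)\n", x$rmse, x$niter))
  invisible(x)
}

#' Predict mapped scores from a fitted logistic mapping
#' @param object a [fit_logistic()] result.
#' @param newdata numeric vector of objective scores.
#' @param ... ignored.
#' @export
predict.logistic_mapping <- function(object, newdata, ...) {
  logistic5(newdata, object$beta)
}

#' Pearson linear correlation of mapped scores with MOS
#'
#' Computed from mean-removed vectors; conventionally applied to the
#' logistic-mapped objective scores.
#'
#' @param qp numeric vector (mapped objective scores).
#' @param mos numeric vector, same length.
#' @return Correlation in `[-1, 1]`.
#' @export
plcc <- function(qp, mos) {
  stopifnot(length(qp) == length(mos), length(qp) >= 2)
  a <- qp - mean(qp)
  b <- mos - mean(mos)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) {
    stop("correlation undefined: an input has zero variance", call. = FALSE)
  }
  sum(a * b) / den
}

#' Spearman rank correlation
#'
#' With no ties this is the classical `1 - 6*sum(d^2) / (m*(m^2-1))` with
#' `d` the per-image rank differences; with ties it falls back to the
#' Pearson correlation of average ranks (the two agree when tie-free).
#'
#' @param Q,mos equal-length numeric vectors (length >= 2).
#' @return Correlation in `[-1, 1]`.
#' @export
srcc <- function(Q, mos) {
  stopifnot(length(Q) == length(mos))
  m <- length(Q)
  if (m < 2) stop("need at least 2 pairs", call. = FALSE)
  rq <- rank(Q); rs <- rank(mos)
  if (anyDuplicated(Q) || anyDuplicated(mos)) {
    return(plcc(rq, rs))
  }
  d <- rq - rs
  1 - 6 * sum(d^2) / (m * (m^2 - 1))
}

#' Kendall rank correlation (tau-a)
#'
#' Exhaustive enumeration of all m(m-1)/2 pairs: `(mc - md) / (0.5*m*(m-1))`
#' with `mc`/`md` the concordant/discordant pair counts.  Tied pairs count
#' toward neither, and the denominator is not tie-corrected (tau-a).
#'
#' @inheritParams srcc
#' @return Correlation in `[-1, 1]`.
#' @export
krcc <- function(Q, mos) {
  stopifnot(length(Q) == length(mos))
  m <- length(Q)
  if (m < 2) stop("need at least 2 pairs", call. = FALSE)
  sq <- sign(outer(Q, Q, "-"))
  ss <- sign(outer(mos, mos, "-"))
  prod_sign <- sq * ss
  upper <- upper.tri(prod_sign)
  mc <- sum(prod_sign[upper] > 0)
  md <- sum(prod_sign[upper] < 0)
  (mc - md) / (0.5 * m * (m - 1))
}

#' Root mean square error between mapped scores and MOS
#' @inheritParams plcc
#' @return `sqrt(mean((qp - mos)^2))`, in MOS units.
#' @export
rmse <- function(qp, mos) {
  if (length(qp) != length(mos)) {
    stop("length mismatch: ", length(qp), " vs ", length(mos), call. = FALSE)
  }
  sqrt(mean((qp - mos)^2))
}

#' Evaluate an objective quality measure against mean opinion scores
#'
#' The standard IQA benchmarking protocol: fit the five-parameter logistic
#' mapping, then report PLCC and RMSE on the mapped scores and SRCC/KRCC on
#' the raw scores (rank criteria are invariant to the monotone mapping),
#' plus the Jarque-Bera statistic of the mapping residuals, which licenses
#' the variance-ratio significance test between measures.
#'
#' @param Q numeric vector of objective scores.
#' @param mos numeric vector of mean opinion scores on the 1-5 scale.
#' @param ids optional image labels (checked against duplicates).
#' @return Object of class `iqa_evaluation`: list with `plcc`, `srcc`,
#'   `krcc`, `rmse`, `beta`, `residuals`, `jb` (a [jarque_bera()] result),
#'   `n`, `ids`.
#' @examples
#' set.seed(2)
#' Q <- runif(30, 0.5, 3)
#' mos <- pmin(5, pmax(1, 1 + 1.3 * Q + rnorm(30, sd = 0.2)))
#' evaluate_iqa(Q, mos)
#' @export
evaluate_iqa <- function(Q, mos, ids = NULL) {
  stopifnot(length(Q) == length(mos))
  if (!is.null(ids)) {
    stopifnot(length(ids) == length(Q))
    if (anyDuplicated(ids)) stop("duplicated image ids", call. = FALSE)
  }
  fit <- fit_logistic(Q, mos)
  qp <- fit$fitted
  res <- fit$residuals
  jb <- if (length(res) >= 8 && stats::sd(res) > 0) jarque_bera(res) else NULL
  structure(
    list(plcc = plcc(qp, mos), srcc = srcc(Q, mos), krcc = krcc(Q, mos),
         rmse = rmse(qp, mos), beta = fit$beta, mapped = qp,
         residuals = res, jb = jb, n = length(Q), ids = ids),
    class = "iqa_evaluation")
}

#' @export
print.iqa_evaluation <- function(x, ...) {
  cat(sprintf("<iqa_evaluation> n = %d images\n", x$n))
  cat(sprintf("  PLCC %.4f  SRCC %.4f  KRCC %.4f  RMSE %.4f\n",
              x$plcc, x$srcc, x$krcc, x$rmse))
  if (!is.null(x$jb)) {
    cat(sprintf("  residual JB %.3f (normality %s at 5%%)\n",
                x$jb$statistic, if (x$jb$reject) "rejected" else "retained"))
  }
  invisible(x)
}
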