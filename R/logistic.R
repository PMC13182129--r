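# maximum-likelihood logistic regression and the performance metrics every
# stage of the simulation studies depends on

as_xy <- function(data, y = NULL) {
  if (inherits(data, "shrink_dataset") ||
      (is.list(data) && !is.null(data$x) && !is.null(data$y))) {
    list(x = data$x, y = data$y)
  } else {
    if (is.null(y)) stop("supply `y` when `data` is a plain matrix")
    list(x = as.matrix(data), y = y)
  }
}

#' Fit an unpenalised logistic regression by maximum likelihood
#'
#' Newton/IRLS iterations (in compiled code) to a mean-score tolerance, with
#' step halving to guarantee likelihood ascent. Non-convergence and quasi-
#' separation (any coefficient beyond 50 on the standardised scale) are
#' flagged, not raised: the simulation engine's exclusion rules decide what to
#' do with such fits.
#'
#' @param data a `shrink_dataset` (or any list with `x` and `y`), or a numeric
#'   matrix with `y` given separately.
#' @param predictors column indices of `x` used as predictors (default: all).
#'   In the simulation studies these are the first `q_meas` columns, the
#'   measured predictors.
#' @param y binary outcome vector when `data` is a matrix.
#' @param tol convergence tolerance on the maximum absolute score divided by
#'   the sample size.
#' @param maxit maximum Newton iterations.
#' @return an object of class `logistic_fit`: `intercept`, `coefficients`,
#'   `predictors`, `loglik_model`, `loglik_null` (closed form), `lr`
#'   (likelihood-ratio statistic), `converged`, `n`.
#' @export
fit_logistic_mle <- function(data, predictors = NULL, y = NULL,
                             tol = 1e-8, maxit = 100L) {
  d <- as_xy(data, y)
  x <- d$x; yy <- as.numeric(d$y)
  n <- length(yy)
  if (all(yy == 0) || all(yy == 1)) {
    stop("outcome is constant: logistic MLE is undefined")
  }
  predictors <- predictors %||% seq_len(ncol(x))
  if (length(predictors) < 1) stop("at least one predictor is required")
  xm <- x[, predictors, drop = FALSE]
  f <- cpp_logit_fit(cbind(1, xm), yy, tol = tol, maxit = as.integer(maxit))
  pbar <- mean(yy)
  ll_null <- n * (pbar * log(pbar) + (1 - pbar) * log(1 - pbar))
  lr <- -2 * (ll_null - f$loglik)
  if (lr < -1e-8) stop("negative likelihood-ratio statistic: fit is invalid")
  structure(list(intercept = f$coef[1],
                 coefficients = f$coef[-1],
                 predictors = predictors,
                 loglik_model = f$loglik,
                 loglik_null = ll_null,
                 lr = max(lr, 0),
                 converged = f$converged,
                 n = n),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> n=%d Q=%d LR=%.3f converged=%s\n",
              x$n, length(x$coefficients), x$lr, x$converged))
  invisible(x)
}

#' Predicted risks or linear predictor from a fitted model
#'
#' @param object a `logistic_fit`.
#' @param newdata a `shrink_dataset` or predictor matrix with at least the
#'   columns the model was fitted on.
#' @param type `"response"` for risks, `"link"` for the linear predictor.
#' @param ... unused.
#' @export
predict.logistic_fit <- function(object, newdata,
                                 type = c("response", "link"), ...) {
  type <- match.arg(type)
  x <- if (is.list(newdata)) newdata$x else as.matrix(newdata)
  lp <- object$intercept +
    drop(x[, object$predictors, drop = FALSE] %*% object$coefficients)
  if (type == "link") lp else plogis(lp)
}

#' Cox-Snell R-squared from a likelihood-ratio statistic
#'
#' `1 - exp(-LR / n)`, the generalised explained-variation measure for a
#' likelihood-based model.
#'
#' @param lr likelihood-ratio statistic (>= 0; tiny negative values from
#'   floating point are clamped to 0).
#' @param n sample size.
#' @return a value in `[0, 1)`.
#' @export
cox_snell_r2 <- function(lr, n) {
  if (any(lr < -1e-8)) stop("likelihood-ratio statistic must be non-negative")
  1 - exp(-pmax(lr, 0) / n)
}

#' Concordance (C-) statistic
#'
#' Probability that a randomly chosen event has a higher predicted risk than a
#' randomly chosen non-event, ties counting one half. Computed from ranks in
#' O(n log n).
#'
#' @param p_hat predicted risks (any monotone score works).
#' @param y binary outcomes with at least one event and one non-event.
#' @return a value in `[0, 1]`; 0.5 is chance, 1 perfect discrimination.
#' @export
c_statistic <- function(p_hat, y) {
  y <- as.numeric(y)
  n1 <- as.numeric(sum(y == 1)); n0 <- as.numeric(sum(y == 0))
  if (n1 == 0 || n0 == 0) stop("need at least one event and one non-event")
  r <- rank(p_hat)  # midranks: ties count one half
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Calibration slope (and intercept) of predicted risks
#'
#' Logistic regression of the observed outcomes on the logit of the predicted
#' risks, with a free intercept. A slope of 1 means the spread of the
#' predictions is right; below 1 means predictions are too extreme
#' (overfitting). Predicted risks are clipped to `[1e-12, 1 - 1e-12]` before
#' the logit so near-boundary predictions from overfit models stay finite.
#'
#' @param p_hat predicted risks in (0, 1). Fractional "observed" outcomes are
#'   accepted in `y`, which marginalises the outcome draw when true event
#'   probabilities are available.
#' @param y outcomes (0/1, or probabilities).
#' @param tol,maxit passed to the Newton fit.
#' @return a list with `slope`, `intercept` and `converged`.
#' @export
calibration_slope <- function(p_hat, y, tol = 1e-8, maxit = 100L) {
  lp <- qlogis(clip01(p_hat))
  if (max(lp) - min(lp) < 1e-12) {
    stop("logit of predictions is constant: calibration slope unidentifiable")
  }
  f <- cpp_calib_slope(lp, as.numeric(y), tol = tol, maxit = as.integer(maxit))
  list(slope = f$slope, intercept = f$intercept, converged = f$converged)
}

#' Apparent and population performance of a fitted model
#'
#' Convenience bundle: C-statistic, Cox-Snell R-squared, calibration slope and
#' intercept of `fit` evaluated on `data`.
#'
#' @param fit a `logistic_fit`.
#' @param data the dataset to evaluate on (the development data gives the
#'   apparent performance; a large validation cohort the population one).
#' @return a list with `c_stat`, `r2_cs`, `calibration_slope`,
#'   `calibration_intercept`.
#' @export
performance_metrics <- function(fit, data) {
  d <- as_xy(data)
  p <- predict(fit, d)
  cal <- calibration_slope(p, d$y)
  # R2 from the refitted likelihood on this data only equals the stored one on
  # the development data itself; report the development-based value there.
  list(c_stat = c_statistic(p, d$y),
       r2_cs = cox_snell_r2(fit$lr, fit$n),
       calibration_slope = cal$slope,
       calibration_intercept = cal$intercept)
}
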