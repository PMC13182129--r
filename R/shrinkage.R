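# the three global shrinkage quantities: heuristic, bootstrap, optimal

#' Heuristic shrinkage factor
#'
#' The closed-form estimator `1 - Q / LR`, where `Q` is the number of
#' predictor parameters (excluding the intercept) and `LR` the likelihood-
#' ratio statistic of the fitted model. No truncation is applied: negative
#' values (possible when `LR < Q`) are returned as-is and handled by the
#' study-level exclusion rules.
#'
#' @param q number of predictor parameters (>= 1).
#' @param lr likelihood-ratio statistic (nonzero).
#' @return the heuristic shrinkage estimate.
#' @export
s_vh <- function(q, lr) {
  stopifnot(q >= 1)
  if (any(lr == 0)) stop("heuristic shrinkage is undefined at LR = 0")
  1 - q / lr
}

#' Bootstrap uniform shrinkage factor
#'
#' For each of `b` replicates: resample the rows of the development data with
#' replacement (same size), refit the logistic model on the replicate, and
#' compute the calibration slope of the replicate model's predictions in the
#' original development data. The estimate is the mean slope over replicates
#' whose refit converged; replicates with a constant resampled outcome or a
#' non-convergent fit are dropped from the mean and counted as failures.
#'
#' @param data development data (`shrink_dataset`, list with `x`/`y`, or a
#'   matrix plus `y`).
#' @param predictors predictor column indices (default: all).
#' @param b number of bootstrap replicates (default 200).
#' @param y outcome vector when `data` is a matrix.
#' @param seed optional seed.
#' @param tol,maxit Newton settings for the refits.
#' @return a list with `s_boot` (mean slope), `failures` (replicate failure
#'   count) and `slopes` (per-replicate slopes, `NA` where failed).
#' @export
s_boot <- function(data, predictors = NULL, b = 200L, y = NULL, seed = NULL,
                   tol = 1e-8, maxit = 100L) {
  stopifnot(b >= 1)
  d <- as_xy(data, y)
  predictors <- predictors %||% seq_len(ncol(d$x))
  design <- cbind(1, d$x[, predictors, drop = FALSE])
  res <- with_seed(seed,
    cpp_boot_shrinkage(design, as.numeric(d$y), as.integer(b),
                       tol = tol, maxit = as.integer(maxit)))
  if (res$failures >= b) stop("every bootstrap replicate failed")
  res
}

#' Optimal shrinkage factor from a validation cohort
#'
#' The calibration slope of the fitted model's predictions in a (large)
#' validation cohort drawn from the same population. With a cohort large
#' enough that sampling it is almost the same as sampling the population,
#' this is the shrinkage multiplier that would make the adjusted model's
#' calibration slope equal 1.
#'
#' @param fit a `logistic_fit` from the development data.
#' @param validation a validation `shrink_dataset` generated from the same
#'   scenario (including any unmeasured predictors in the truth).
#' @param use_true_p if `TRUE` and the cohort carries true event
#'   probabilities, the slope is computed against them (marginalising the
#'   outcome draw); default uses the sampled outcomes, as in a real
#'   validation study.
#' @return the calibration slope (a scalar).
#' @export
s_opt <- function(fit, validation, use_true_p = FALSE) {
  p <- predict(fit, validation)
  yy <- if (use_true_p && !is.null(validation$true_p)) validation$true_p else
    validation$y
  calibration_slope(p, yy)$slope
}

#' Apply a global shrinkage factor to a fitted model
#'
#' Multiplies the predictor coefficients by `s` and re-estimates the intercept
#' on the development data (intercept-only logistic fit with the shrunken
#' linear predictor as offset) so the mean predicted risk is preserved.
#' Provided as a modelling convenience; the simulation studies compare
#' estimators of the shrinkage factor itself.
#'
#' @param fit a `logistic_fit`.
#' @param s shrinkage factor.
#' @param data the development data used to re-estimate the intercept.
#' @return a `logistic_fit` with shrunken coefficients and revised intercept.
#' @export
apply_shrinkage <- function(fit, s, data) {
  d <- as_xy(data)
  lp <- drop(d$x[, fit$predictors, drop = FALSE] %*% (s * fit$coefficients))
  # one-parameter Newton for the intercept given the offset
  b0 <- fit$intercept
  for (i in 1:50) {
    p <- plogis(b0 + lp)
    g <- sum(d$y - p)
    h <- sum(p * (1 - p))
    step <- g / h
    b0 <- b0 + step
    if (abs(step) < 1e-12) break
  }
  out <- fit
  out$intercept <- b0
  out$coefficients <- s * fit$coefficients
  out$shrinkage <- s
  out
}
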