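# minimum sample size for developing a logistic prediction model:
# the analytic criterion targeting the heuristic shrinkage factor, the
# C-statistic -> Cox-Snell R2 conversion, and the simulation-based search
# that targets the expected optimal shrinkage directly

#' Analytic minimum sample size targeting the heuristic shrinkage factor
#'
#' Evaluates `N = p / ((S - 1) * ln(1 - R2 / S))` and rounds up to a whole
#' number of participants. `p` is the number of candidate predictor
#' parameters prior to any variable selection, `S` the desired global
#' shrinkage (e.g. 0.9, reflecting low overfitting) and `R2` the anticipated
#' Cox-Snell R-squared of the model. If `r2_adj` is not supplied it is derived
#' from an anticipated C-statistic and outcome prevalence via [c_to_r2()].
#'
#' @param p number of predictor parameters (>= 1).
#' @param s_target desired shrinkage factor in (0, 1).
#' @param r2_adj anticipated Cox-Snell R-squared; must be below `s_target`.
#' @param c_expected anticipated C-statistic (used with `prevalence` when
#'   `r2_adj` is missing).
#' @param prevalence anticipated outcome proportion.
#' @param sim_n,seed passed to [c_to_r2()] when the conversion is needed.
#' @return the minimum sample size (integer).
#' @export
samplesize_analytic <- function(p, s_target = 0.9, r2_adj = NULL, c_expected = NULL,
                    prevalence = NULL, sim_n = 1e6, seed = NULL) {
  stopifnot(p >= 1, s_target > 0, s_target < 1)
  if (is.null(r2_adj)) {
    if (is.null(c_expected) || is.null(prevalence)) {
      stop("supply either r2_adj, or c_expected together with prevalence")
    }
    r2_adj <- c_to_r2(c_expected, prevalence, sim_n = sim_n, seed = seed)
  }
  if (r2_adj >= s_target) {
    stop("anticipated R-squared must be below the target shrinkage ",
         "(log of a non-positive argument otherwise)")
  }
  as.integer(ceiling(p / ((s_target - 1) * log(1 - r2_adj / s_target))))
}

#' Convert an anticipated C-statistic to a Cox-Snell R-squared
#'
#' Simulates a large cohort in which the linear predictor is normal within
#' outcome groups with unit variance and means separated by
#' `sqrt(2) * qnorm(c)` (the separation that makes the score's concordance
#' equal `c`), outcomes drawn at the given prevalence; fits the logistic
#' model of outcome on linear predictor and returns its Cox-Snell R-squared
#' `1 - exp(-LR / n)`.
#'
#' @param cstat anticipated C-statistic in (0.5, 1).
#' @param prevalence anticipated outcome proportion in (0, 1).
#' @param sim_n simulated cohort size (default 1e6).
#' @param seed optional seed.
#' @return the Cox-Snell R-squared (scalar).
#' @export
c_to_r2 <- function(cstat, prevalence, sim_n = 1e6, seed = NULL) {
  if (cstat <= 0.5 || cstat >= 1) stop("cstat must lie in (0.5, 1)")
  stopifnot(prevalence > 0, prevalence < 1, sim_n >= 100)
  delta <- sqrt(2) * qnorm(cstat)
  with_seed(seed, {
    y <- rbinom(sim_n, 1L, prevalence)
    lp <- rnorm(sim_n, mean = y * delta, sd = 1)
    f <- cpp_logit_fit(cbind(1, lp), as.numeric(y))
    pbar <- mean(y)
    ll_null <- sim_n * (pbar * log(pbar) + (1 - pbar) * log(1 - pbar))
    cox_snell_r2(-2 * (ll_null - f$loglik), sim_n)
  })
}

#' Settings for the simulation-based sample-size search
#'
#' @param m_reps development-model replicates per candidate sample size.
#' @param m_reps_final replicates for the confirmation evaluation once a
#'   candidate is within tolerance (larger, to control Monte-Carlo noise at
#'   the decision point).
#' @param validation_n size of the simulated validation cohort on which the
#'   calibration slope of each replicate model is evaluated (against the true
#'   event probabilities, so no outcome noise enters from the validation
#'   side).
#' @param tolerance required closeness of the Monte-Carlo mean calibration
#'   slope to the target shrinkage.
#' @param max_evals cap on candidate-size evaluations before the search
#'   reports non-convergence.
#' @param sigma_sim_n cohort size used to calibrate the linear-predictor scale
#'   to the anticipated C-statistic.
#' @param n_min smallest admissible development size (default `max(20, 2p)`).
#' @return a list of class `samplesize_sim_settings`.
#' @export
samplesize_sim_settings <- function(m_reps = 500L, m_reps_final = 1000L,
                            validation_n = 1e5, tolerance = 0.005,
                            max_evals = 40L, sigma_sim_n = 2e5,
                            n_min = NULL) {
  structure(list(m_reps = as.integer(m_reps),
                 m_reps_final = as.integer(m_reps_final),
                 validation_n = validation_n,
                 tolerance = tolerance,
                 max_evals = as.integer(max_evals),
                 sigma_sim_n = sigma_sim_n,
                 n_min = n_min),
            class = "samplesize_sim_settings")
}

#' Simulation-based minimum sample size targeting the optimal shrinkage
#'
#' Iteratively simulates development cohorts of candidate size `n` — `p`
#' independent standard-normal predictors with equal coefficients whose scale
#' is calibrated so the population C-statistic equals `c_expected`, intercept
#' set to the anticipated prevalence — fits the unpenalised logistic model to
#' each, and averages the calibration slopes of the fitted models in a large
#' validation cohort. The search is bisection on `n`, seeded by the analytic
#' criterion [samplesize_analytic()] and bracketed by geometric expansion; a candidate
#' whose Monte-Carlo mean slope falls within `tolerance` of `s_target` is
#' re-evaluated with more replicates before being accepted. Validation-side
#' calibration slopes are computed against true event probabilities, so the
#' only Monte-Carlo noise is the development-data draw.
#'
#' @param p number of predictor parameters.
#' @param c_expected anticipated C-statistic in (0.5, 1).
#' @param prevalence anticipated outcome proportion.
#' @param s_target target expected shrinkage (default 0.9; must be < 1).
#' @param settings a [samplesize_sim_settings()].
#' @param seed optional seed; the whole search is deterministic given it.
#' @return a list with `n_sim` (the selected size), `converged`, `sigma`
#'   (calibrated linear-predictor standard deviation) and `evaluations`
#'   (data frame of every candidate evaluated: `n`, `mean_sopt`, `m`).
#' @export
samplesize_sim <- function(p, c_expected, prevalence, s_target = 0.9,
                        settings = samplesize_sim_settings(), seed = NULL) {
  stopifnot(p >= 1, prevalence > 0, prevalence < 1)
  if (s_target >= 1) stop("target shrinkage of 1 or more needs unbounded n")
  if (s_target <= 0) stop("target shrinkage must be positive")
  if (c_expected <= 0.5 || c_expected >= 1) {
    stop("c_expected must lie in (0.5, 1)")
  }
  n_min <- settings$n_min %||% max(20L, 2L * p)
  with_seed(seed, {
    # calibrate the linear-predictor scale to the anticipated C-statistic
    zcal <- rnorm(settings$sigma_sim_n)
    sigma <- calibrate_lp_scale(1, prevalence, c_expected, zcal,
                                tolerance = 5e-4)$k
    rm(zcal)
    # one fixed validation cohort (common random numbers across candidates)
    zval <- matrix(rnorm(settings$validation_n * p), ncol = p)
    eta_val <- drop(zval %*% rep(sigma / sqrt(p), p))
    b0 <- tune_intercept(eta_val, prevalence)
    p_val <- plogis(b0 + eta_val)
    bcoef <- rep(sigma / sqrt(p), p)

    eval_n <- function(n, m) {
      slopes <- numeric(m)
      ok <- logical(m)
      for (i in seq_len(m)) {
        x <- matrix(rnorm(n * p), n, p)
        pr <- plogis(b0 + drop(x %*% bcoef))
        yy <- rbinom(n, 1L, pr)
        if (all(yy == 0L) || all(yy == 1L)) next
        f <- cpp_logit_fit(cbind(1, x), as.numeric(yy))
        if (!f$converged) next
        lp <- f$coef[1] + drop(zval %*% f$coef[-1])
        cs <- cpp_calib_slope(lp, p_val)
        if (!cs$converged) next
        slopes[i] <- cs$slope
        ok[i] <- TRUE
      }
      if (!any(ok)) return(NA_real_)
      mean(slopes[ok])
    }

    evals <- data.frame(n = integer(), mean_sopt = numeric(), m = integer())
    record <- function(n, s, m) {
      evals[nrow(evals) + 1L, ] <<- list(as.integer(n), s, as.integer(m))
    }

    # seed point from the analytic criterion (internal R2 conversion)
    r2_seed <- c_to_r2(c_expected, prevalence, sim_n = 5e5)
    n0 <- tryCatch(samplesize_analytic(p, s_target, r2_adj = r2_seed),
                   error = function(e) 4L * p)
    lo <- NA_real_; hi <- NA_real_
    n_cur <- max(n_min, n0)
    converged <- FALSE
    n_sim <- NA_integer_
    while (nrow(evals) < settings$max_evals) {
      est <- eval_n(n_cur, settings$m_reps)
      record(n_cur, est, settings$m_reps)
      if (is.na(est)) { n_cur <- min(2 * n_cur, 1e7); next }
      if (abs(est - s_target) <= settings$tolerance) {
        confirm <- eval_n(n_cur, settings$m_reps_final)
        record(n_cur, confirm, settings$m_reps_final)
        if (!is.na(confirm) &&
            abs(confirm - s_target) <= settings$tolerance) {
          n_sim <- n_cur
          converged <- TRUE
          break
        }
        est <- confirm
        if (is.na(est)) { n_cur <- min(2 * n_cur, 1e7); next }
      }
      if (est < s_target) lo <- max(lo, n_cur, na.rm = TRUE)
      else hi <- min(hi, n_cur, na.rm = TRUE)
      if (is.na(lo) && !is.na(hi) && n_cur <= n_min) {
        n_sim <- as.integer(n_min)  # even the floor overshoots the target
        break
      }
      if (!is.na(lo) && !is.na(hi) && hi - lo <= 1) break  # bracket exhausted
      n_cur <- if (is.na(lo)) {
        max(n_min, floor(n_cur / 2))
      } else if (is.na(hi)) {
        ceiling(n_cur * 2)
      } else {
        round((lo + hi) / 2)
      }
    }
    if (is.na(n_sim)) {
      # not converged: report the evaluated size whose estimate came closest
      done <- evals[!is.na(evals$mean_sopt), ]
      n_sim <- if (nrow(done)) {
        done$n[which.min(abs(done$mean_sopt - s_target))]
      } else {
        as.integer(n_cur)
      }
    }
    list(n_sim = as.integer(n_sim), converged = converged, sigma = sigma,
         evaluations = evals)
  })
}
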