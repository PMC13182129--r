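#' Settings for random scenario generation
#'
#' A scenario is a frozen set of simulation parameters: numbers of measured
#' and unmeasured predictors, their covariance, true log odds ratios, target
#' outcome proportion and development sample size. Scenarios are drawn at
#' random so the parameter space is covered without hand-picking.
#'
#' @param covariance_mode `"random_psd"` for a random positive semi-definite
#'   correlation structure between all predictors, `"identity"` for
#'   uncorrelated predictors.
#' @param dgm `"default"` draws coefficients uniformly so the achievable
#'   C-statistic grows with the number of predictors; `"independent_c"`
#'   rescales the coefficients to a target C-statistic drawn from
#'   `U(0.55, 0.95)` (with no unmeasured predictors), which decouples the
#'   predictor count from model discrimination.
#' @param q_max maximum number of measured (and unmeasured) predictors;
#'   counts are uniform random integers in `1..q_max`.
#' @param beta_range range of the uniform distribution for the raw log odds
#'   ratios.
#' @param prop_range range of the uniform distribution for the target outcome
#'   proportion.
#' @param n_dev_offset,weibull_shape,weibull_scale,n_dev_cap development
#'   sample size is drawn as `round(n_dev_offset + W)` with
#'   `W ~ Weibull(weibull_shape, weibull_scale)`, redrawn from scratch until
#'   the total is at most `n_dev_cap`. The default gives sizes between 100 and
#'   5000 with small samples most frequent.
#' @param target_c_range range of the uniform target C-statistic
#'   (`independent_c` mechanism only).
#' @param rescale settings for the coefficient rescaling search, see
#'   [rescale_settings()].
#' @param max_redraws cap on sample-size redraws before signalling a broken
#'   random stream.
#' @return a list of class `scenario_config`.
#' @export
scenario_config <- function(covariance_mode = c("random_psd", "identity"),
                            dgm = c("default", "independent_c"),
                            q_max = 30L,
                            beta_range = c(-0.5, 0.5),
                            prop_range = c(0.05, 0.95),
                            n_dev_offset = 100,
                            weibull_shape = 0.5,
                            weibull_scale = 2500,
                            n_dev_cap = 5000,
                            target_c_range = c(0.55, 0.95),
                            rescale = rescale_settings(),
                            max_redraws = 10000L) {
  structure(list(covariance_mode = match.arg(covariance_mode),
                 dgm = match.arg(dgm),
                 q_max = as.integer(q_max),
                 beta_range = beta_range,
                 prop_range = prop_range,
                 n_dev_offset = n_dev_offset,
                 weibull_shape = weibull_shape,
                 weibull_scale = weibull_scale,
                 n_dev_cap = n_dev_cap,
                 target_c_range = target_c_range,
                 rescale = rescale,
                 max_redraws = as.integer(max_redraws)),
            class = "scenario_config")
}

new_scenario <- function(q_meas, q_unmeas, beta, beta0, omega, prop, n_dev,
                         covariance_mode, dgm = "default", target_c = NA_real_,
                         seed = NA_integer_) {
  sc <- structure(list(q_meas = as.integer(q_meas),
                       q_unmeas = as.integer(q_unmeas),
                       beta = as.numeric(beta),
                       beta0 = as.numeric(beta0),
                       omega = omega,
                       prop = as.numeric(prop),
                       n_dev = as.integer(n_dev),
                       covariance_mode = covariance_mode,
                       dgm = dgm,
                       target_c = target_c,
                       seed = seed),
                  class = "shrink_scenario")
  validate_scenario(sc)
  sc
}

validate_scenario <- function(sc) {
  q <- sc$q_meas + sc$q_unmeas
  stopifnot(sc$q_meas >= 1, sc$q_unmeas >= 0,
            length(sc$beta) == q,
            is.matrix(sc$omega), nrow(sc$omega) == q, ncol(sc$omega) == q,
            sc$prop > 0, sc$prop < 1,
            sc$n_dev >= 1)
  if (max(abs(sc$omega - t(sc$omega))) > 1e-10) {
    stop("scenario covariance must be symmetric")
  }
  if (min(eigen(sc$omega, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-8) {
    stop("scenario covariance must be positive semi-definite")
  }
  invisible(sc)
}

#' @export
print.shrink_scenario <- function(x, ...) {
  cat(sprintf(paste0("<shrink_scenario> q_meas=%d q_unmeas=%d n_dev=%d ",
                     "prop=%.3f cov=%s dgm=%s\n"),
              x$q_meas, x$q_unmeas, x$n_dev, x$prop, x$covariance_mode, x$dgm))
  invisible(x)
}

# development sample size: offset + Weibull, redrawn until <= cap
draw_n_dev <- function(config) {
  for (i in seq_len(config$max_redraws)) {
    n <- config$n_dev_offset +
      rweibull(1, shape = config$weibull_shape, scale = config$weibull_scale)
    if (n <= config$n_dev_cap) return(as.integer(round(n)))
  }
  stop("sample-size draw exceeded ", config$max_redraws,
       " redraws; random stream looks broken")
}

#' Random correlation matrix with positive semi-definite structure
#'
#' Draws a q x q factor matrix with independent standard-normal entries, forms
#' its Gram matrix and rescales to unit diagonal. The result is a valid
#' correlation matrix inducing random dependence between all pairs of
#' variables.
#'
#' @param q dimension (>= 1).
#' @param seed optional seed; `NULL` uses the current random stream.
#' @return a symmetric positive semi-definite matrix with unit diagonal.
#' @export
random_psd_correlation <- function(q, seed = NULL) {
  if (q < 1) stop("dimension must be at least 1")
  q <- as.integer(q)
  with_seed(seed, {
    if (q == 1L) {
      matrix(1, 1, 1)
    } else {
      a <- matrix(rnorm(q * q), q, q)
      g <- tcrossprod(a)
      d <- 1 / sqrt(diag(g))
      r <- g * tcrossprod(d)
      (r + t(r)) / 2
    }
  })
}

#' Draw a random simulation scenario
#'
#' Predictor counts are uniform random integers, log odds ratios uniform in
#' `beta_range`, outcome proportion uniform in `prop_range` with the intercept
#' set to its logit, the covariance either a random PSD correlation matrix or
#' the identity, and the development sample size offset-plus-Weibull
#' (truncated by redraw). With `dgm = "independent_c"` there are no unmeasured
#' predictors and the coefficients are rescaled to a uniform random target
#' C-statistic, making predictor count and discrimination independent.
#'
#' @param config a [scenario_config()].
#' @param seed optional seed; the same seed always yields the same scenario.
#' @return a `shrink_scenario`.
#' @export
sample_scenario <- function(config = scenario_config(), seed = NULL) {
  with_seed(seed, {
    if (config$dgm == "independent_c") {
      sample_scenario_alt_(config, seed)
    } else {
      q_meas <- sample.int(config$q_max, 1)
      q_unmeas <- sample.int(config$q_max, 1)
      q <- q_meas + q_unmeas
      beta <- runif(q, config$beta_range[1], config$beta_range[2])
      prop <- runif(1, config$prop_range[1], config$prop_range[2])
      omega <- if (config$covariance_mode == "identity") diag(q) else
        random_psd_correlation(q)
      n_dev <- draw_n_dev(config)
      new_scenario(q_meas, q_unmeas, beta, qlogis(prop), omega, prop, n_dev,
                   config$covariance_mode, dgm = "default",
                   seed = seed %||% NA_integer_)
    }
  })
}

# body of the alternative mechanism; runs inside the caller's seed context
sample_scenario_alt_ <- function(config, seed) {
  q_meas <- sample.int(config$q_max, 1)
  beta_raw <- runif(q_meas, config$beta_range[1], config$beta_range[2])
  prop <- runif(1, config$prop_range[1], config$prop_range[2])
  target_c <- runif(1, config$target_c_range[1], config$target_c_range[2])
  omega <- if (config$covariance_mode == "identity") diag(q_meas) else
    random_psd_correlation(q_meas)
  n_dev <- draw_n_dev(config)
  beta <- rescale_coefficients_to_c(beta_raw, prop, target_c, omega = omega,
                                    settings = config$rescale)
  new_scenario(q_meas, 0L, beta, qlogis(prop), omega, prop, n_dev,
               config$covariance_mode, dgm = "independent_c",
               target_c = target_c, seed = seed %||% NA_integer_)
}

#' Draw a scenario under the mechanism that decouples predictor count from
#' discrimination
#'
#' Convenience wrapper for [sample_scenario()] with `dgm = "independent_c"`:
#' no unmeasured predictors, coefficients rescaled to a target C-statistic
#' drawn from `U(0.55, 0.95)`.
#'
#' @inheritParams sample_scenario
#' @export
sample_scenario_alt <- function(config = scenario_config(dgm = "independent_c"),
                                seed = NULL) {
  config$dgm <- "independent_c"
  sample_scenario(config, seed)
}

#' Generate a dataset from a scenario
#'
#' Predictors are multivariate normal with mean zero and the scenario
#' covariance; the true risk is the logistic transform of the full linear
#' predictor over all (measured and unmeasured) predictors; outcomes are
#' independent Bernoulli draws from the true risks.
#'
#' @param scenario a `shrink_scenario`.
#' @param n number of rows (default: the scenario's development sample size).
#' @param seed optional seed.
#' @return a list of class `shrink_dataset` with elements `x` (n x Q matrix),
#'   `y` (0/1 vector) and `true_p` (true event probabilities).
#' @export
generate_dataset <- function(scenario, n = scenario$n_dev, seed = NULL) {
  stopifnot(n >= 1)
  m <- psd_sqrt(scenario$omega)
  q <- length(scenario$beta)
  with_seed(seed, {
    x <- matrix(rnorm(n * q), n, q) %*% m
    eta <- scenario$beta0 + drop(x %*% scenario$beta)
    true_p <- plogis(eta)
    y <- rbinom(n, 1L, true_p)
    structure(list(x = x, y = y, true_p = true_p), class = "shrink_dataset")
  })
}

#' Settings for the coefficient rescaling search
#'
#' @param sim_n size of the simulated predictor cohort on which the
#'   population C-statistic of a candidate scaling is evaluated.
#' @param tolerance required closeness of the achieved C-statistic to the
#'   target.
#' @param max_iter cap on bracket doublings / bisection steps.
#' @return a list of class `rescale_settings`.
#' @export
rescale_settings <- function(sim_n = 1e5, tolerance = 0.002, max_iter = 80L) {
  structure(list(sim_n = sim_n, tolerance = tolerance,
                 max_iter = as.integer(max_iter)),
            class = "rescale_settings")
}

#' Rescale logistic coefficients to hit a target C-statistic
#'
#' Finds a positive scalar `k` such that the logistic model with coefficients
#' `k * beta` (intercept retuned to the requested prevalence) attains the
#' target population C-statistic, and returns `k * beta`. Because the linear
#' predictor of a multivariate-normal design is itself normal, the search
#' simulates only its standard-normal shape and evaluates the
#' outcome-marginalised concordance, which is smooth and strictly increasing
#' in `k`; the root is found by bracket doubling plus bisection.
#'
#' @param beta coefficient vector with at least one nonzero entry.
#' @param prevalence target outcome proportion in (0, 1).
#' @param target_c target C-statistic in (0.5, 1).
#' @param omega predictor covariance (default identity).
#' @param settings a [rescale_settings()].
#' @param seed optional seed for the simulated cohort.
#' @return the rescaled coefficient vector, with the multiplier in attribute
#'   `"k"` and the achieved C-statistic in attribute `"achieved_c"`.
#' @export
rescale_coefficients_to_c <- function(beta, prevalence, target_c,
                                      omega = NULL,
                                      settings = rescale_settings(),
                                      seed = NULL) {
  if (all(beta == 0)) {
    stop("beta is the zero vector: the C-statistic is fixed at 0.5 and the ",
         "target is unreachable")
  }
  if (target_c <= 0.5 || target_c >= 1) stop("target_c must lie in (0.5, 1)")
  sd_lp <- if (is.null(omega)) sqrt(sum(beta^2)) else
    sqrt(drop(crossprod(beta, omega %*% beta)))
  if (sd_lp <= 0) stop("linear predictor has zero variance under omega")
  with_seed(seed, {
    z <- rnorm(settings$sim_n)
    res <- calibrate_lp_scale(sd_lp, prevalence, target_c, z,
                              tolerance = settings$tolerance,
                              max_iter = settings$max_iter)
    out <- res$k * beta
    attr(out, "k") <- res$k
    attr(out, "achieved_c") <- res$c
    out
  })
}

# Find k > 0 so that eta = k * sd_lp * z (intercept tuned to prev) has
# population C equal to target_c. Monotone in k; bracket by doubling, then
# bisect to `tolerance` on the C scale.
calibrate_lp_scale <- function(sd_lp, prev, target_c, z, tolerance = 0.002,
                               max_iter = 80L) {
  cstat_at <- function(k) {
    eta <- k * sd_lp * z
    b0 <- tune_intercept(eta, prev)
    population_cstat(eta, plogis(b0 + eta))
  }
  lo <- NA_real_; hi <- NA_real_
  k <- 1
  ck <- cstat_at(k)
  it <- 0L
  while (is.na(lo) || is.na(hi)) {
    if (ck < target_c) {
      lo <- k
      if (is.na(hi)) { k <- k * 2; ck <- cstat_at(k) }
    } else {
      hi <- k
      if (is.na(lo)) { k <- k / 2; ck <- cstat_at(k) }
    }
    it <- it + 1L
    if (it > max_iter) {
      stop("failed to bracket the target C-statistic after ", max_iter,
           " doublings")
    }
  }
  for (i in seq_len(max_iter)) {
    k <- sqrt(lo * hi)  # geometric midpoint: scale is multiplicative
    ck <- cstat_at(k)
    if (abs(ck - target_c) <= tolerance) break
    if (ck < target_c) lo <- k else hi <- k
  }
  list(k = k, c = ck)
}

#' Serialize a scenario to JSON
#'
#' All fields round-trip losslessly (matrices stored row-major), so runs are
#' restartable and auditable.
#'
#' @param scenario a `shrink_scenario`.
#' @param path optional file path; if omitted the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
scenario_to_json <- function(scenario, path = NULL) {
  q <- length(scenario$beta)
  obj <- list(q_meas = scenario$q_meas, q_unmeas = scenario$q_unmeas,
              beta = scenario$beta, beta0 = scenario$beta0,
              omega = as.numeric(t(scenario$omega)), omega_dim = q,
              prop = scenario$prop, n_dev = scenario$n_dev,
              covariance_mode = scenario$covariance_mode, dgm = scenario$dgm,
              target_c = scenario$target_c, seed = scenario$seed)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read a scenario from JSON
#' @param x a file path or JSON string produced by [scenario_to_json()].
#' @return a `shrink_scenario`.
#' @export
scenario_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  q <- obj$omega_dim
  new_scenario(obj$q_meas, obj$q_unmeas, obj$beta, obj$beta0,
               matrix(obj$omega, q, q, byrow = TRUE), obj$prop, obj$n_dev,
               obj$covariance_mode, dgm = obj$dgm,
               target_c = obj$target_c %||% NA_real_,
               seed = obj$seed %||% NA_integer_)
}
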