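# Monte-Carlo engine for the two simulation studies: per-scenario iteration
# loops, bias / Monte-Carlo-error metrics, exclusion rules and stratified
# summary tables

#' Population standard deviation with divisor n
#'
#' The Monte-Carlo standard deviation of a performance measure is defined with
#' divisor equal to the number of iterations (not n - 1); the Monte-Carlo
#' standard error is this divided by the square root of the iteration count.
#'
#' @param x numeric vector (length >= 1).
#' @return the divisor-n standard deviation.
#' @export
scenario_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

#' Run one scenario of the shrinkage-estimator study
#'
#' Executes the full per-scenario protocol: generate one large validation
#' cohort; fit the model there to obtain the population C-statistic and
#' Cox-Snell R-squared (the performance the model would achieve were sample
#' size unlimited); then, per iteration, generate a development dataset of the
#' scenario's size, fit the unpenalised logistic model on the measured
#' predictors, record the heuristic and bootstrap shrinkage estimates and the
#' apparent performance, and compute the optimal shrinkage as the calibration
#' slope in the validation cohort. Bias of each estimator is the mean of
#' (estimate - optimal shrinkage) across iterations; its Monte-Carlo standard
#' error is the divisor-n standard deviation over the square root of the
#' iteration count.
#'
#' @param scenario a `shrink_scenario`.
#' @param iterations number of development datasets (default 250).
#' @param validation_n validation cohort size (default 1e6).
#' @param b_boot bootstrap replicates per iteration (default 200).
#' @param seed optional seed; iteration streams are derived from it.
#' @return a list of class `scenario_result`: population metrics, the
#'   per-iteration `records` data frame, and the bias / sd / MCE summaries.
#' @export
run_study1_scenario <- function(scenario, iterations = 250L,
                                validation_n = 1e6, b_boot = 200L,
                                seed = NULL) {
  stopifnot(iterations >= 1)
  seed <- seed %||% derive_seed(sample.int(2^30, 1), 0L)
  q_meas <- scenario$q_meas
  validation <- generate_dataset(scenario, validation_n,
                                 seed = derive_seed(seed, 0L))
  pop_fit <- fit_logistic_mle(validation, predictors = seq_len(q_meas))
  p_pop <- predict(pop_fit, validation)
  c_pop <- c_statistic(p_pop, validation$y)
  r2_pop <- cox_snell_r2(pop_fit$lr, pop_fit$n)
  prev_pop <- mean(validation$y)

  rec <- data.frame(iteration = seq_len(iterations), s_vh = NA_real_,
                    s_boot = NA_real_, s_opt = NA_real_, c_app = NA_real_,
                    r2_app = NA_real_, boot_failures = NA_integer_,
                    fit_converged = FALSE, events = NA_integer_)
  for (m in seq_len(iterations)) {
    it_seed <- derive_seed(seed, m)
    dev <- generate_dataset(scenario, scenario$n_dev, seed = it_seed)
    rec$events[m] <- sum(dev$y)
    if (all(dev$y == 0L) || all(dev$y == 1L)) next
    fit <- fit_logistic_mle(dev, predictors = seq_len(q_meas))
    rec$fit_converged[m] <- fit$converged
    if (!fit$converged) next
    p_app <- predict(fit, dev)
    rec$c_app[m] <- c_statistic(p_app, dev$y)
    rec$r2_app[m] <- cox_snell_r2(fit$lr, fit$n)
    rec$s_vh[m] <- s_vh(q_meas, fit$lr)
    sb <- tryCatch(
      s_boot(dev, predictors = seq_len(q_meas), b = b_boot,
             seed = derive_seed(it_seed, 1L)),
      error = function(e) list(s_boot = NA_real_, failures = b_boot))
    rec$s_boot[m] <- sb$s_boot
    rec$boot_failures[m] <- sb$failures
    rec$s_opt[m] <- calibration_slope(predict(fit, validation),
                                      validation$y)$slope
  }

  used <- rec$fit_converged & !is.na(rec$s_boot)
  dev_vh <- rec$s_vh[used] - rec$s_opt[used]
  dev_boot <- rec$s_boot[used] - rec$s_opt[used]
  n_used <- sum(used)
  structure(list(
    scenario = scenario,
    c_pop = c_pop, r2_pop = r2_pop, prev_pop = prev_pop,
    epp = mean(rec$events, na.rm = TRUE) / q_meas,
    records = rec,
    n_iter = iterations, n_used = n_used,
    fit_failures = sum(!rec$fit_converged),
    boot_fail_rate = sum(rec$boot_failures, na.rm = TRUE) /
      (b_boot * max(n_used, 1)),
    mean_svh = mean(rec$s_vh[used]),
    mean_sboot = mean(rec$s_boot[used]),
    mean_sopt = mean(rec$s_opt[used]),
    mean_r2app = mean(rec$r2_app[used]),
    bias_vh = mean(dev_vh), bias_boot = mean(dev_boot),
    sd_vh = scenario_sd(dev_vh), sd_boot = scenario_sd(dev_boot),
    mce_vh = scenario_sd(dev_vh) / sqrt(length(dev_vh)),
    mce_boot = scenario_sd(dev_boot) / sqrt(length(dev_boot))),
    class = "scenario_result")
}

#' Run one scenario of the sample-size study
#'
#' Generates the validation cohort, measures the population C-statistic and
#' Cox-Snell R-squared of the measured-predictor model, derives the analytic
#' minimum sample size (targeting shrinkage `s_target` with the population
#' R-squared) and the simulation-based size (with the population C-statistic
#' and realized validation prevalence); then, per iteration, simulates one
#' development dataset at each size, fits the model and records the optimal
#' shrinkage in the validation cohort. Bias is the mean of
#' (optimal shrinkage - `s_target`).
#'
#' @inheritParams run_study1_scenario
#' @param s_target targeted shrinkage (default 0.9).
#' @param nsim_settings [samplesize_sim_settings()] for the embedded search; the
#'   default is a lighter profile than the standalone one since the search
#'   runs once per scenario.
#' @return a list of class `scenario_result2`.
#' @export
run_study2_scenario <- function(scenario, iterations = 250L,
                                validation_n = 1e6, s_target = 0.9,
                                nsim_settings = samplesize_sim_settings(
                                  m_reps = 100L, m_reps_final = 300L,
                                  validation_n = 2e4, tolerance = 0.01,
                                  max_evals = 25L, sigma_sim_n = 5e4),
                                seed = NULL) {
  seed <- seed %||% derive_seed(sample.int(2^30, 1), 0L)
  q_meas <- scenario$q_meas
  validation <- generate_dataset(scenario, validation_n,
                                 seed = derive_seed(seed, 0L))
  pop_fit <- fit_logistic_mle(validation, predictors = seq_len(q_meas))
  c_pop <- c_statistic(predict(pop_fit, validation), validation$y)
  r2_pop <- cox_snell_r2(pop_fit$lr, pop_fit$n)
  prev_pop <- mean(validation$y)

  n_original <- tryCatch(samplesize_analytic(q_meas, s_target, r2_adj = r2_pop),
                         error = function(e) NA_integer_)
  ns <- if (c_pop > 0.51) {
    tryCatch(samplesize_sim(q_meas, c_pop, prev_pop, s_target,
                         settings = nsim_settings,
                         seed = derive_seed(seed, 1L, 7L)),
             error = function(e) list(n_sim = NA_integer_, converged = FALSE))
  } else {
    list(n_sim = NA_integer_, converged = FALSE)
  }

  rec <- data.frame(iteration = seq_len(iterations),
                    s_opt_original = NA_real_, s_opt_sim = NA_real_)
  one_sopt <- function(n, it_seed) {
    dev <- generate_dataset(scenario, n, seed = it_seed)
    if (all(dev$y == 0L) || all(dev$y == 1L)) return(NA_real_)
    fit <- fit_logistic_mle(dev, predictors = seq_len(q_meas))
    if (!fit$converged) return(NA_real_)
    calibration_slope(predict(fit, validation), validation$y)$slope
  }
  for (m in seq_len(iterations)) {
    if (!is.na(n_original)) {
      rec$s_opt_original[m] <- one_sopt(n_original, derive_seed(seed, m, 1L))
    }
    if (ns$converged && !is.na(ns$n_sim)) {
      rec$s_opt_sim[m] <- one_sopt(ns$n_sim, derive_seed(seed, m, 2L))
    }
  }
  structure(list(
    scenario = scenario,
    c_pop = c_pop, r2_pop = r2_pop, prev_pop = prev_pop,
    n_original = n_original, n_sim = ns$n_sim,
    nsim_converged = isTRUE(ns$converged),
    records = rec,
    mean_sopt_original = mean(rec$s_opt_original, na.rm = TRUE),
    mean_sopt_sim = if (isTRUE(ns$converged))
      mean(rec$s_opt_sim, na.rm = TRUE) else NA_real_,
    bias_original = mean(rec$s_opt_original - s_target, na.rm = TRUE),
    bias_sim = if (isTRUE(ns$converged))
      mean(rec$s_opt_sim - s_target, na.rm = TRUE) else NA_real_,
    s_target = s_target),
    class = "scenario_result2")
}

result_row <- function(res, id) {
  sc <- res$scenario
  base <- data.frame(scenario_id = id, q_meas = sc$q_meas,
                     q_unmeas = sc$q_unmeas, n_dev = sc$n_dev,
                     prop = sc$prop, covariance_mode = sc$covariance_mode,
                     dgm = sc$dgm, c_pop = res$c_pop, r2_pop = res$r2_pop,
                     prev_pop = res$prev_pop)
  if (inherits(res, "scenario_result")) {
    cbind(base, data.frame(
      epp = res$epp, n_used = res$n_used, fit_failures = res$fit_failures,
      boot_fail_rate = res$boot_fail_rate, mean_svh = res$mean_svh,
      mean_sboot = res$mean_sboot, mean_sopt = res$mean_sopt,
      mean_r2app = res$mean_r2app, bias_vh = res$bias_vh,
      bias_boot = res$bias_boot, sd_vh = res$sd_vh, sd_boot = res$sd_boot,
      mce_vh = res$mce_vh, mce_boot = res$mce_boot))
  } else {
    cbind(base, data.frame(
      n_original = res$n_original, n_sim = res$n_sim,
      nsim_converged = res$nsim_converged,
      mean_sopt_original = res$mean_sopt_original,
      mean_sopt_sim = res$mean_sopt_sim,
      bias_original = res$bias_original, bias_sim = res$bias_sim))
  }
}

#' Run a whole simulation study over randomly drawn scenarios
#'
#' Draws `n_scenarios` scenarios from the configured generator and runs the
#' per-scenario protocol for the chosen study. Every scenario gets its own
#' derived seed, so results are identical regardless of execution order.
#'
#' @param config a [run_config()].
#' @param progress print one line per scenario.
#' @return a list with `scenarios` (one summary row per scenario),
#'   `records` (per-iteration rows, with `scenario_id`) and `config`.
#' @export
run_study <- function(config, progress = FALSE) {
  scfg <- scenario_config(covariance_mode = config$covariance_mode,
                          dgm = config$dgm)
  rows <- vector("list", config$n_scenarios)
  recs <- vector("list", config$n_scenarios)
  for (k in seq_len(config$n_scenarios)) {
    sc_seed <- derive_seed(config$master_seed, k, 1L)
    run_seed <- derive_seed(config$master_seed, k, 2L)
    scenario <- sample_scenario(scfg, seed = sc_seed)
    res <- if (config$study == 1) {
      run_study1_scenario(scenario, iterations = config$iterations,
                          validation_n = config$validation_n,
                          b_boot = config$b_boot, seed = run_seed)
    } else {
      run_study2_scenario(scenario, iterations = config$iterations,
                          validation_n = config$validation_n,
                          s_target = config$s_target,
                          nsim_settings = config$nsim_settings,
                          seed = run_seed)
    }
    rows[[k]] <- result_row(res, k)
    r <- res$records
    r$scenario_id <- k
    recs[[k]] <- r
    if (progress) {
      message(sprintf("scenario %d/%d seed=%d c_pop=%.3f", k,
                      config$n_scenarios, sc_seed, res$c_pop))
    }
  }
  list(scenarios = do.call(rbind, rows), records = do.call(rbind, recs),
       config = config)
}

#' Exclusion rules for the shrinkage-estimator study
#'
#' Removes extreme, non-representative scenarios: negative mean heuristic or
#' bootstrap shrinkage, negative mean apparent R-squared, mean bootstrap
#' shrinkage above 2, or a bootstrap-refit failure rate above the threshold.
#'
#' @param scenarios the `scenarios` data frame from [run_study()] (study 1).
#' @param boot_fail_threshold maximum tolerated proportion of failed bootstrap
#'   refits (default 0.05).
#' @return a list with `kept` and `excluded` (the latter with an
#'   `exclusion_reason` column); together they partition the input.
#' @export
apply_exclusions_study1 <- function(scenarios, boot_fail_threshold = 0.05) {
  reason <- rep(NA_character_, nrow(scenarios))
  mark <- function(cond, why) {
    cond[is.na(cond)] <- TRUE  # undefined summaries are themselves extreme
    ifelse(is.na(reason) & cond, why, reason)
  }
  reason <- mark(scenarios$mean_svh < 0, "mean_s_vh<0")
  reason <- mark(scenarios$mean_sboot < 0, "mean_s_boot<0")
  reason <- mark(scenarios$mean_sboot > 2, "mean_s_boot>2")
  reason <- mark(scenarios$mean_r2app < 0, "mean_r2_app<0")
  reason <- mark(scenarios$boot_fail_rate > boot_fail_threshold,
                 "bootstrap_failures")
  kept <- scenarios[is.na(reason), , drop = FALSE]
  excluded <- scenarios[!is.na(reason), , drop = FALSE]
  excluded$exclusion_reason <- reason[!is.na(reason)]
  list(kept = kept, excluded = excluded)
}

#' Exclusion rules for the sample-size study
#'
#' Removes scenarios whose mean optimal shrinkage (under either sample size)
#' is negative or above 2, and routes scenarios where the simulation-based
#' search did not converge to their own stratum rather than dropping them.
#'
#' @param scenarios the `scenarios` data frame from [run_study()] (study 2).
#' @return a list with `kept`, `excluded` (with reasons) and `not_converged`.
#' @export
apply_exclusions_study2 <- function(scenarios) {
  bad_orig <- !is.na(scenarios$mean_sopt_original) &
    (scenarios$mean_sopt_original < 0 | scenarios$mean_sopt_original > 2)
  bad_sim <- scenarios$nsim_converged & !is.na(scenarios$mean_sopt_sim) &
    (scenarios$mean_sopt_sim < 0 | scenarios$mean_sopt_sim > 2)
  bad_na <- is.na(scenarios$mean_sopt_original) | is.na(scenarios$n_original)
  reason <- ifelse(bad_na, "n_original_undefined",
            ifelse(bad_orig, "mean_s_opt_original_out_of_range",
            ifelse(bad_sim, "mean_s_opt_sim_out_of_range", NA_character_)))
  excluded <- scenarios[!is.na(reason), , drop = FALSE]
  excluded$exclusion_reason <- reason[!is.na(reason)]
  rest <- scenarios[is.na(reason), , drop = FALSE]
  list(kept = rest[rest$nsim_converged, , drop = FALSE],
       not_converged = rest[!rest$nsim_converged, , drop = FALSE],
       excluded = excluded)
}

#' Stratified summary table of a per-scenario statistic
#'
#' Mean, standard deviation and percentiles of a chosen per-scenario column,
#' overall and stratified into bins of the population C-statistic (default
#' width-0.05 bins from 0.55 to 0.9). Percentiles use linear interpolation
#' between order statistics.
#'
#' @param scenarios a per-scenario data frame (typically the `kept` part).
#' @param value name of the column to summarise (e.g. `"bias_vh"`), or
#'   `"magnitude_<col>"` for its absolute value.
#' @param strata_edges bin edges for the population C-statistic.
#' @param probs percentile levels (default 2.5/25/50/75/97.5).
#' @return a data frame with one row per stratum plus an `"All"` row:
#'   `stratum`, `n_scenarios`, `mean`, `sd` and one `p*` column per
#'   percentile; empty strata give `NA` statistics.
#' @export
summarize_results <- function(scenarios, value,
                              strata_edges = seq(0.55, 0.9, by = 0.05),
                              probs = c(0.025, 0.25, 0.5, 0.75, 0.975)) {
  col <- if (startsWith(value, "magnitude_")) {
    abs(scenarios[[sub("^magnitude_", "", value)]])
  } else {
    scenarios[[value]]
  }
  if (is.null(col)) stop("unknown statistic column: ", value)
  one <- function(label, x) {
    x <- x[!is.na(x)]
    qs <- if (length(x)) quantile(x, probs, type = 7, names = FALSE) else
      rep(NA_real_, length(probs))
    out <- data.frame(stratum = label, statistic = value,
                      n_scenarios = length(x),
                      mean = if (length(x)) mean(x) else NA_real_,
                      sd = if (length(x) > 1) sd(x) else NA_real_)
    qn <- paste0("p", vapply(probs, function(pp)
      gsub("\\.", "_", format(100 * pp, trim = TRUE)), character(1)))
    out[qn] <- as.list(qs)
    out
  }
  rows <- list(one("All", col))
  for (i in seq_len(length(strata_edges) - 1)) {
    lo <- strata_edges[i]; hi <- strata_edges[i + 1]
    sel <- !is.na(scenarios$c_pop) & scenarios$c_pop >= lo &
      scenarios$c_pop < hi
    rows[[i + 1]] <- one(sprintf("%.2f<=C_pop<%.2f", lo, hi), col[sel])
  }
  do.call(rbind, rows)
}
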