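# run configuration, (de)serialization and the end-to-end pipeline writer

#' Configuration of a simulation run
#'
#' @param study 1 (shrinkage-estimator comparison) or 2 (sample-size
#'   criteria).
#' @param dgm `"default"` or `"independent_c"` (see [scenario_config()]).
#' @param covariance_mode `"random_psd"` or `"identity"`.
#' @param n_scenarios number of random scenarios.
#' @param iterations development datasets per scenario (default 250).
#' @param validation_n validation cohort size (default 1e6).
#' @param b_boot bootstrap replicates per iteration (study 1; default 200).
#' @param s_target targeted shrinkage for study 2 (default 0.9).
#' @param master_seed one master seed; all scenario and iteration streams are
#'   derived from it.
#' @param output_dir where [run_simulation()] writes its artifacts.
#' @param boot_fail_threshold exclusion threshold on the bootstrap-refit
#'   failure rate.
#' @param strata_edges C-statistic bin edges for the summary tables.
#' @param nsim_settings [samplesize_sim_settings()] for the per-scenario search in
#'   study 2.
#' @return a list of class `run_config`.
#' @export
run_config <- function(study = 1, dgm = c("default", "independent_c"),
                       covariance_mode = c("random_psd", "identity"),
                       n_scenarios = 100L, iterations = 250L,
                       validation_n = 1e6, b_boot = 200L, s_target = 0.9,
                       master_seed = 1L, output_dir = NULL,
                       boot_fail_threshold = 0.05,
                       strata_edges = seq(0.55, 0.9, by = 0.05),
                       nsim_settings = samplesize_sim_settings(
                         m_reps = 100L, m_reps_final = 300L,
                         validation_n = 2e4, tolerance = 0.01,
                         max_evals = 25L, sigma_sim_n = 5e4)) {
  stopifnot(study %in% c(1, 2), n_scenarios >= 1, iterations >= 1,
            validation_n >= 100, b_boot >= 1)
  structure(list(study = as.integer(study), dgm = match.arg(dgm),
                 covariance_mode = match.arg(covariance_mode),
                 n_scenarios = as.integer(n_scenarios),
                 iterations = as.integer(iterations),
                 validation_n = validation_n, b_boot = as.integer(b_boot),
                 s_target = s_target, master_seed = as.integer(master_seed),
                 output_dir = output_dir,
                 boot_fail_threshold = boot_fail_threshold,
                 strata_edges = strata_edges,
                 nsim_settings = nsim_settings),
            class = "run_config")
}

#' Write a run configuration to YAML
#' @param config a [run_config()].
#' @param path output file.
#' @export
write_run_config <- function(config, path) {
  obj <- unclass(config)
  obj$nsim_settings <- unclass(obj$nsim_settings)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path a YAML file written by [write_run_config()] (or hand-edited).
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  ns <- do.call(samplesize_sim_settings, obj$nsim_settings %||% list())
  run_config(study = obj$study %||% 1, dgm = obj$dgm %||% "default",
             covariance_mode = obj$covariance_mode %||% "random_psd",
             n_scenarios = obj$n_scenarios %||% 100L,
             iterations = obj$iterations %||% 250L,
             validation_n = obj$validation_n %||% 1e6,
             b_boot = obj$b_boot %||% 200L,
             s_target = obj$s_target %||% 0.9,
             master_seed = obj$master_seed %||% 1L,
             output_dir = obj$output_dir,
             boot_fail_threshold = obj$boot_fail_threshold %||% 0.05,
             strata_edges = obj$strata_edges %||% seq(0.55, 0.9, 0.05),
             nsim_settings = ns)
}

#' Run a study end to end and write its artifacts
#'
#' Runs [run_study()], applies the exclusion rules, builds the stratified
#' summary tables and writes everything under `config$output_dir`:
#' `config.yaml` (the resolved configuration), `scenarios.csv`,
#' `records.csv`, `summary_*.csv` and `log.txt` (one line per scenario with
#' its seed and exclusion status). Numeric CSVs keep full double precision.
#'
#' @param config a [run_config()] with `output_dir` set.
#' @param progress print per-scenario progress.
#' @return (invisibly) a list with the in-memory results, exclusions and
#'   summaries.
#' @export
run_simulation <- function(config, progress = FALSE) {
  out_dir <- config$output_dir
  if (is.null(out_dir)) stop("config$output_dir must be set")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- run_study(config, progress = progress)
  mce_tab <- NULL
  if (config$study == 1) {
    excl <- apply_exclusions_study1(res$scenarios,
                                    config$boot_fail_threshold)
    stats <- c("bias_vh", "bias_boot", "magnitude_bias_vh",
               "magnitude_bias_boot")
    summaries <- lapply(stats, function(s)
      summarize_results(excl$kept, s, config$strata_edges))
    # the Monte-Carlo-error table uses its own percentile set
    mce_tab <- do.call(rbind, lapply(c("mce_vh", "mce_boot"), function(s)
      summarize_results(excl$kept, s, config$strata_edges,
                        probs = c(0.5, 0.9, 0.99))))
  } else {
    excl <- apply_exclusions_study2(res$scenarios)
    stats <- c("mean_sopt_original", "mean_sopt_sim", "bias_original",
               "bias_sim", "magnitude_bias_original", "magnitude_bias_sim")
    summaries <- lapply(stats, function(s)
      summarize_results(excl$kept, s, config$strata_edges))
  }
  summary_tab <- do.call(rbind, summaries)
  write_run_config(config, file.path(out_dir, "config.yaml"))
  write.csv(res$scenarios, file.path(out_dir, "scenarios.csv"),
            row.names = FALSE)
  write.csv(res$records, file.path(out_dir, "records.csv"),
            row.names = FALSE)
  write.csv(summary_tab, file.path(out_dir, "summary.csv"),
            row.names = FALSE)
  if (!is.null(mce_tab)) {
    write.csv(mce_tab, file.path(out_dir, "summary_mce.csv"),
              row.names = FALSE)
  }
  if (nrow(excl$excluded)) {
    write.csv(excl$excluded, file.path(out_dir, "excluded.csv"),
              row.names = FALSE)
  }
  log_lines <- sprintf(
    "scenario=%d seed=%d c_pop=%.4f status=%s",
    res$scenarios$scenario_id,
    vapply(res$scenarios$scenario_id, function(k)
      derive_seed(config$master_seed, k, 1L), integer(1)),
    res$scenarios$c_pop,
    ifelse(res$scenarios$scenario_id %in% excl$excluded$scenario_id,
           "excluded", "kept"))
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(list(results = res, exclusions = excl, summary = summary_tab))
}
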