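# diagnostic figures: mean-level agreement between estimator and optimal
# shrinkage, and within-scenario instability

#' @importFrom rlang .data
NULL

#' Scatter of mean estimated vs mean optimal shrinkage across scenarios
#'
#' One point per scenario: the mean shrinkage estimate against the mean
#' optimal shrinkage, with the 45-degree identity line as reference. Points
#' can be coloured by a scenario property (population R-squared, C-statistic,
#' predictor count, events per predictor, sample size), or dichotomised at a
#' C-statistic threshold to show where the estimator flips from under- to
#' over-estimation.
#'
#' @param scenarios a per-scenario data frame (kept scenarios of study 1).
#' @param estimator `"vh"` or `"boot"`.
#' @param color_by one of `"r2_pop"`, `"c_pop"`, `"q_meas"`, `"epp"`,
#'   `"n_dev"`, or `NULL`.
#' @param threshold optional C-statistic cut; when given, points are coloured
#'   by which side of it `c_pop` falls.
#' @return a ggplot object.
#' @export
plot_mean_agreement <- function(scenarios, estimator = c("vh", "boot"),
                                color_by = "c_pop", threshold = NULL) {
  estimator <- match.arg(estimator)
  xcol <- paste0("mean_s", estimator)
  allowed <- c("r2_pop", "c_pop", "q_meas", "epp", "n_dev")
  df <- data.frame(est = scenarios[[xcol]], opt = scenarios$mean_sopt)
  if (!is.null(threshold)) {
    df$colour <- factor(ifelse(scenarios$c_pop >= threshold,
                               sprintf("C_pop >= %.2f", threshold),
                               sprintf("C_pop < %.2f", threshold)))
    lab <- "C_pop group"
  } else if (!is.null(color_by)) {
    if (!color_by %in% allowed) {
      stop("unknown colour selector: ", color_by)
    }
    df$colour <- scenarios[[color_by]]
    lab <- color_by
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$est, y = .data$opt)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey40") +
    ggplot2::labs(x = sprintf("mean(S_%s)", estimator),
                  y = "mean(S_opt)") +
    ggplot2::theme_minimal()
  if (!is.null(threshold) || !is.null(color_by)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour),
                                 alpha = 0.7, size = 1.2) +
      ggplot2::labs(colour = lab)
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.7, size = 1.2)
  }
  p
}

#' Within-scenario instability of the shrinkage quantities
#'
#' Per-iteration scatter of the optimal shrinkage against the bootstrap
#' estimate for selected scenarios, with horizontal guides at the 2.5th,
#' 25th, 50th, 75th and 97.5th percentiles of the optimal shrinkage. Shows
#' that an estimator can be right on average yet far off in any single
#' development sample.
#'
#' @param records per-iteration records (columns `scenario_id`, `s_boot`,
#'   `s_opt`).
#' @param scenario_ids which scenarios to facet (default: all present).
#' @return a ggplot object.
#' @export
plot_instability <- function(records, scenario_ids = NULL) {
  if (!is.null(scenario_ids)) {
    records <- records[records$scenario_id %in% scenario_ids, , drop = FALSE]
  }
  records <- records[!is.na(records$s_opt) & !is.na(records$s_boot), ,
                     drop = FALSE]
  if (!nrow(records)) stop("no usable iteration records to plot")
  qs <- do.call(rbind, lapply(split(records, records$scenario_id),
    function(d) {
      data.frame(scenario_id = d$scenario_id[1],
                 q = quantile(d$s_opt, c(0.025, 0.25, 0.5, 0.75, 0.975),
                              names = FALSE))
    }))
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$s_boot, y = .data$s_opt)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.9) +
    ggplot2::geom_hline(data = qs, ggplot2::aes(yintercept = .data$q),
                        linetype = 3, colour = "grey40") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::facet_wrap(~scenario_id) +
    ggplot2::labs(x = "S_boot (per iteration)", y = "S_opt (per iteration)") +
    ggplot2::theme_minimal()
}

#' Save a plot to file
#'
#' Thin wrapper over [ggplot2::ggsave()] used by the command-line interface;
#' the device is inferred from the file extension.
#'
#' @param plot a ggplot object.
#' @param path output file (`.pdf` or `.png`).
#' @param width,height size in inches.
#' @export
save_plot <- function(plot, path, width = 7, height = 5) {
  ggplot2::ggsave(path, plot, width = width, height = height)
  invisible(path)
}
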