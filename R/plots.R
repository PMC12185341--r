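# ggplot2 graphics for cohorts, traces and classification reports.

#' Group-mean calibrated traces with dispersion bands
#'
#' Plots the mean intensity profile per group (diagnosis, optionally split by
#' treatment) along the calibrated arc length, with a mean +/- SD ribbon —
#' the standard way to compare AIS profile shapes between conditions.
#'
#' @param traces Calibrated long trace tibble (see [calibrate_traces()]).
#' @param colour_by Metadata column used for colour (default diagnosis).
#' @param facet_by Optional metadata column to facet by (e.g. treatment).
#' @return A ggplot object.
#' @export
plot_mean_traces <- function(traces, colour_by = "diagnosis", facet_by = NULL) {
  stopifnot(colour_by %in% names(traces))
  grp <- c(colour_by, facet_by, "position_px")
  summ <- traces %>%
    group_by(across(all_of(grp))) %>%
    summarise(mean = mean(.data$intensity), sd = sd(.data$intensity),
              .groups = "drop")
  p <- ggplot2::ggplot(summ, ggplot2::aes(
    x = .data$position_px, y = .data$mean,
    colour = .data[[colour_by]], fill = .data[[colour_by]])) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Distance along AIS (px)",
                  y = "Fluorescence intensity (a.u.)",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(facet_by)) {
    p <- p + ggplot2::facet_wrap(stats::as.formula(paste("~", facet_by)))
  }
  p
}

#' @describeIn plot_mean_traces Autoplot of a synthetic cohort's raw traces.
#' @param object A `synthetic_cohort`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.synthetic_cohort <- function(object, ...) {
  if (is.null(object$traces)) abort("Cohort has no traces to plot.")
  plot_mean_traces(object$traces)
}

#' @exportS3Method ggplot2::autoplot
autoplot.rf_report <- function(object, ...) {
  df <- object$per_repeat
  ggplot2::ggplot(df, ggplot2::aes(x = "", y = .data$accuracy)) +
    ggplot2::geom_jitter(width = 0.05, alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.3,
                          colour = "red") +
    ggplot2::labs(
      x = NULL, y = "Test accuracy (%)",
      title = sprintf("%s: %.1f%% ± %.1f%%",
                      if (is.null(object$task)) "classification" else object$task,
                      object$mean_accuracy, object$sd_accuracy)) +
    ggplot2::theme_minimal()
}

#' Accuracy summary table as a bar plot
#'
#' @param summary_table Tibble with columns `task_label`, `mean_accuracy`,
#'   `sd_accuracy` (as written by [run_experiment()]).
#' @return A ggplot object.
#' @export
plot_accuracy_table <- function(summary_table) {
  ggplot2::ggplot(summary_table, ggplot2::aes(
    x = .data$task_label, y = .data$mean_accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_accuracy - .data$sd_accuracy,
      ymax = .data$mean_accuracy + .data$sd_accuracy), width = 0.2) +
    ggplot2::geom_hline(yintercept = 50, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Mean test accuracy (%)") +
    ggplot2::theme_minimal()
}
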