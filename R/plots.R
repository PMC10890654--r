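#' Plot lap-speed traces
#'
#' Lap speed against lap index for each runner, faceted by day, with the
#' per-day cohort-mean linear trend overlaid. The visual signature of a
#' positive pacing strategy is the downward trend line.
#'
#' @param cohort A cohort tibble.
#' @param course A [race_course()].
#' @param runners Optional character vector restricting the runners
#'   shown.
#' @return A ggplot object.
#' @export
plot_lap_speeds <- function(cohort, course = cohort_course(cohort),
                            runners = NULL) {
  d <- cohort
  if (!is.null(runners)) d <- dplyr::filter(d, .data$runner_id %in% runners)
  d <- dplyr::mutate(d, speed = course$lap_distance / .data$lap_time_s)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lap, y = .data$speed)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$runner_id),
                       alpha = 0.35, linewidth = 0.3) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linetype = "dashed", colour = "black") +
    ggplot2::facet_wrap(~day, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Lap", y = "Lap speed (m/s)") +
    ggplot2::theme_minimal()
}

#' Forest plot of ICC reliability with confidence intervals
#'
#' @param object A `pacing_reliability` tibble from
#'   [reliability_report()].
#' @param ... Unused.
#' @return A ggplot object: per-variable ICC point estimates with 95%
#'   CI whiskers and the poor/moderate/good/excellent band cut points.
#' @exportS3Method ggplot2::autoplot
autoplot.pacing_reliability <- function(object, ...) {
  d <- dplyr::filter(object, !.data$degenerate)
  d$variable <- factor(d$variable, levels = rev(d$variable))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$icc, y = .data$variable)) +
    ggplot2::geom_vline(xintercept = c(0.5, 0.75, 0.9),
                        linetype = "dotted", colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$icc_ci_low, xmax = .data$icc_ci_high),
      height = 0.2
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "ICC (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Box plots of a pacing variable across performance groups
#'
#' @param vars_tbl Per-(runner, day) tibble from [pacing_variables()].
#' @param groups Group assignments from [bin_performance_groups()].
#' @param variable Which variable to plot (default `"cv"`).
#' @return A ggplot object, faceted by day.
#' @export
plot_group_comparison <- function(vars_tbl, groups, variable = "cv") {
  d <- dplyr::inner_join(vars_tbl, groups[, c("runner_id", "group")],
                         by = "runner_id")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group,
                                  y = .data[[variable]])) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::facet_wrap(~day, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = toupper(variable)) +
    ggplot2::theme_minimal()
}
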