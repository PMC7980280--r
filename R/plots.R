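# ggplot2 views of recordings, traces, pooled responses and the joint
# behavior-physiology distribution.

#' @export
autoplot.fp_recording <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(c("signal", "control"), names_to = "channel",
                        values_to = "fluorescence")
  ggplot(df, aes(x = .data$time_s, y = .data$fluorescence,
                 color = .data$channel)) +
    geom_line(linewidth = 0.3) +
    scale_color_manual(values = c(signal = "#2e7d32", control = "grey55")) +
    labs(x = "time (s)", y = "fluorescence (a.u.)",
         title = "Raw two-channel recording") +
    theme_minimal()
}

#' @export
autoplot.fp_trace <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$time_s, y = .data$z)) +
    geom_line(linewidth = 0.3, color = "#2e7d32") +
    labs(x = "time (s)", y = "z-scored dF/F",
         title = "Processed trace") +
    theme_minimal()
}

#' @export
autoplot.fp_pooled <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$rel_time_s, y = .data$mean_z)) +
    geom_ribbon(aes(ymin = .data$lwr, ymax = .data$upr), alpha = 0.25,
                fill = "#1565c0") +
    geom_line(color = "#1565c0") +
    geom_vline(xintercept = 0, linetype = "dashed", linewidth = 0.3) +
    labs(x = "time from CS onset (s)", y = "mean z dF/F",
         title = sprintf("Pooled response (n = %d trials)",
                         attr(object, "n_trials"))) +
    theme_minimal()
}

#' Pooled responses per cohort and session
#'
#' @param pooled Table from [run_pipeline()]'s `$pooled` (columns `cohort`,
#'   `session`, `rel_time_s`, `mean_z`, `lwr`, `upr`).
#' @return A ggplot.
#' @export
plot_pooled_responses <- function(pooled) {
  ggplot(pooled, aes(x = .data$rel_time_s, y = .data$mean_z,
                     color = .data$cohort, fill = .data$cohort)) +
    geom_ribbon(aes(ymin = .data$lwr, ymax = .data$upr), alpha = 0.2,
                color = NA) +
    geom_line() +
    geom_vline(xintercept = c(0, 0.25), linetype = "dashed",
               linewidth = 0.3) +
    facet_wrap(~session, labeller = label_both) +
    labs(x = "time from CS onset (s)", y = "mean z dF/F") +
    theme_minimal()
}

#' Joint behavior-physiology scatter
#'
#' Mean CS--US z against z-scored post-perturbation step time, per trial,
#' colored by cohort: a responsive cohort sits high on the physiology axis
#' and low on the step-time axis.
#'
#' @param analysis Per-trial analysis table with `z_mean_csus`, `z_post`,
#'   `cohort`.
#' @return A ggplot.
#' @export
plot_cohort_scatter <- function(analysis) {
  ggplot(analysis, aes(x = .data$z_post, y = .data$z_mean_csus,
                       color = .data$cohort)) +
    geom_point(alpha = 0.5, size = 1) +
    stat_ellipse(level = 0.9) +
    labs(x = "z post-perturbation step time", y = "mean z dF/F (CS-US)") +
    theme_minimal()
}

#' Session-wise metric distributions by cohort
#'
#' @param analysis Per-trial analysis table.
#' @param metric Metric column to display.
#' @return A ggplot.
#' @export
plot_session_metric <- function(analysis, metric = "z_mean_csus") {
  ggplot(analysis, aes(x = factor(.data$session), y = .data[[metric]],
                       fill = .data$cohort)) +
    geom_boxplot(outlier.size = 0.6, alpha = 0.8) +
    labs(x = "learning session", y = metric) +
    theme_minimal()
}
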