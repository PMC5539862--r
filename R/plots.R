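#' Histogram of repeated-windowing p-values
#'
#' The analogue of the p-value histograms used to read off whether a test
#' rejects across random windowings.
#'
#' @param object An `sw_pvalue_summary`.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sw_pvalue_summary <- function(object, bins = 20, ...) {
  df <- tibble(p_value = object$p_values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p_value)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0, fill = "grey35") +
    ggplot2::geom_vline(xintercept = 0.05, linetype = 2, colour = "red") +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(x = "p-value", y = "count",
                  title = sprintf("%s, %s-axis (J = %d)", object$test,
                                  object$axis, object$n_reps)) +
    ggplot2::theme_minimal()
}

#' Boxplots of the network-depth sweep
#'
#' @param object An `sw_sweep` tibble from [layer_sweep()].
#' @param ... Unused.
#' @return A ggplot of patient-level misclassification rate per depth.
#' @export
autoplot.sw_sweep <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = factor(.data$layers),
                               y = .data$misclassification)) +
    ggplot2::geom_boxplot(fill = "grey80") +
    ggplot2::labs(x = "hidden layers", y = "misclassified patients (rate)") +
    ggplot2::theme_minimal()
}

#' Bar chart of per-stage success rates
#'
#' @param object An `sw_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sw_report <- function(object, ...) {
  df <- object$by_stage
  df$stage <- factor(df$stage, levels = c(stage_levels(), "total"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$success_rate)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::scale_y_continuous(labels = function(v) paste0(100 * v, "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "success rate", title = object$method) +
    ggplot2::theme_minimal()
}

#' Plot one recording's acceleration traces
#'
#' @param cohort An `sw_cohort`.
#' @param recording_id Which recording to plot.
#' @return A ggplot of the three axes against time.
#' @export
plot_recording <- function(cohort, recording_id) {
  i <- match(recording_id, cohort$recording_id)
  if (is.na(i)) abort(paste0("unknown recording: ", recording_id))
  rec <- cohort$data[[i]] %>%
    tidyr::pivot_longer(c("ax", "ay", "az"), names_to = "axis",
                        values_to = "acceleration")
  ggplot2::ggplot(rec, ggplot2::aes(x = .data$t, y = .data$acceleration)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~axis, ncol = 1) +
    ggplot2::labs(x = "time (s)", y = expression(acceleration ~ (m/s^2)),
                  title = recording_id) +
    ggplot2::theme_minimal()
}
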