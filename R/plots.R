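#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cohort trace as stacked state occupancy
#'
#' @param object A [build_trace()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("pf", "pd", "dead"),
                              names_to = "state", values_to = "occupancy")
  long$state <- factor(long$state, levels = c("dead", "pd", "pf"),
                       labels = c("Dead", "Progressed", "Progression-free"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$occupancy,
                                     fill = .data$state)) +
    ggplot2::geom_area(alpha = 0.85) +
    ggplot2::labs(x = "Time (months)", y = "State occupancy", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Tornado diagram of a one-way sensitivity sweep
#'
#' @param object A [one_way_sweep()] result.
#' @param top Number of widest parameters to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tornado_table <- function(object, top = 10, ...) {
  df <- dplyr::slice_head(dplyr::filter(object, !is.na(.data$width)), n = top)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_low, xend = .data$icer_high,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = attr(object, "icer_base"), linetype = 2) +
    ggplot2::labs(x = "ICER ($/QALY)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve plot
#'
#' @param object A [ceac()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ceac_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$wtp,
                                       y = .data$prob_cost_effective)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness-to-pay ($/QALY)",
                  y = "Probability cost-effective") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness plane of PSA draws
#'
#' @param object A [psa_run()] result.
#' @param wtp Willingness-to-pay line to draw, USD/QALY.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psa_samples <- function(object, wtp = 150000, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$incremental_qaly,
                                       y = .data$incremental_cost)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6, colour = "steelblue") +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = 2) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost ($)") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier step plot
#'
#' @param object A [km_estimate()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.km_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival") +
    ggplot2::theme_minimal()
}
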