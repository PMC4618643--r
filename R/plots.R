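#' Plot concentration-time profiles of a simulated study
#'
#' One panel per analyte, geometric mean concentration by treatment and
#' nominal time on the day(s) sampled; BLQ samples are excluded.
#'
#' @param object A `pk_study` from [simulate_crossover()].
#' @param day Which study day to plot (default 1).
#' @param log_scale Semilog y-axis (default FALSE).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pk_study
#' @export
autoplot.pk_study <- function(object, day = 1, log_scale = FALSE, ...) {
  df <- object$concentrations |>
    dplyr::filter(.data$day == !!day, !.data$blq) |>
    dplyr::group_by(.data$analyte, .data$treatment, .data$nominal_time) |>
    dplyr::summarise(
      concentration = exp(mean(log(.data$concentration))), .groups = "drop"
    )
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$nominal_time, y = .data$concentration,
    colour = .data$treatment
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$analyte), scales = "free_y") +
    ggplot2::labs(x = "Time (h)",
                  y = "Geometric mean concentration (µg/mL)",
                  colour = "Treatment",
                  title = sprintf("Day %d concentration-time profiles", day))
  if (log_scale) p <- p + ggplot2::scale_y_log10()
  p
}

#' Forest plot of geometric LS-mean ratios against the equivalence band
#'
#' @param object A `pk_ddi` from [ddi_analysis()].
#' @param ... Unused.
#' @return A ggplot object: point estimates with CI bars on a log-scaled
#'   percent axis, the no-interaction band shaded.
#' @method autoplot pk_ddi
#' @export
autoplot.pk_ddi <- function(object, ...) {
  df <- object$results |>
    dplyr::mutate(label = sprintf("%s %s (day %d)", .data$analyte,
                                  .data$parameter, .data$day))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ratio_percent,
                                   y = .data$label)) +
    ggplot2::annotate("rect", xmin = object$limits_percent[1],
                      xmax = object$limits_percent[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.12) +
    ggplot2::geom_vline(xintercept = 100, linetype = 2) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low_percent,
                                         xmax = .data$ci_high_percent),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = sprintf("Geometric LS-mean ratio, %% (%.0f%% CI)",
                  100 * object$conf_level),
      y = NULL
    )
}
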