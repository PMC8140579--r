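# ggplot2 visualisations for each result type.

#' @export
autoplot.loglogistic_fit <- function(object, n = 200, ...) {
  df <- object$data
  rng <- range(df$tt)
  curve <- tibble(
    temperature_C = seq(rng[1], rng[2], length.out = n),
    value = loglogistic_eval(seq(rng[1], rng[2], length.out = n),
                             object$c, object$d, object$b, object$u)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tt, y = .data$yy)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(x = .data$temperature_C, y = .data$value),
                       colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$u, linetype = "dashed") +
    ggplot2::labs(x = "Temperature (°C)", y = "Damage",
                  title = sprintf("Log-logistic fit (%s), LT50 = %.1f °C",
                                  object$constraint_mode, object$u)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gompertz_fit <- function(object, n = 200, ...) {
  df <- object$data
  rng <- range(df$tt)
  curve <- tibble(
    temperature_C = seq(rng[1], rng[2], length.out = n),
    value = gompertz_eval(seq(rng[1], rng[2], length.out = n), object$b, object$k)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tt, y = .data$yy)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(x = .data$temperature_C, y = .data$value),
                       colour = "steelblue") +
    ggplot2::geom_vline(xintercept = lt_max_gompertz(object), linetype = "dashed") +
    ggplot2::labs(x = "Temperature (°C)", y = "Adjusted index (%)",
                  title = sprintf("Gompertz fit, LT50 = %.1f, LTmax = %.1f °C",
                                  lt_p_gompertz(object, 50), lt_max_gompertz(object))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.deming_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$outlier), alpha = 0.7) +
    ggplot2::geom_abline(slope = object$slope, intercept = 0, colour = "firebrick") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "orange")) +
    ggplot2::labs(x = "Autoclave conductivity (µS/cm)",
                  y = "Liquid-nitrogen conductivity (µS/cm)",
                  title = sprintf("Zero-intercept Deming: slope = %.3f", object$slope),
                  colour = "Outlier") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.threshold_grid <- function(object, metric = c("rmse", "bias", "correlation"), ...) {
  metric <- match.arg(metric)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$vd_p, y = .data$el_p,
                                       fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Visual-damage threshold (%)",
                  y = "Electrolyte-leakage threshold (%)",
                  fill = metric,
                  title = "Threshold-grid agreement, leakage vs visual damage") +
    ggplot2::theme_minimal()
}

#' Plot a DTA trace with called exotherms
#'
#' @param trace A `dta_trace`.
#' @param peaks Optional peak tibble from [detect_exotherms()].
#' @return A ggplot.
#' @export
plot_dta_trace <- function(trace, peaks = NULL) {
  p <- ggplot2::ggplot(as_tibble(trace),
                       ggplot2::aes(x = .data$temperature_C, y = .data$voltage_mV)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Temperature (°C)", y = "Voltage (mV)",
                  title = "DTA cooling trace") +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks) > 0) {
    p <- p + ggplot2::geom_vline(
      data = peaks,
      ggplot2::aes(xintercept = .data$temperature_C, colour = .data$klass),
      linetype = "dashed"
    ) +
      ggplot2::labs(colour = "Exotherm")
  }
  p
}
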