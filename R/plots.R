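#' Plot a spatial-temporal concentration map
#'
#' Heatmap of concentration over axial position and time, with
#' isoconcentration contours at 1, 5, 10, 30 and 40 µM by default.
#'
#' @param object A `spatiotemporal_map` or `concentration_field`.
#' @param contours Contour levels (µM).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.concentration_field <- function(object, contours = c(1, 5, 10, 30, 40),
                                         ...) {
  df <- tidy(object)
  df$t_h <- df$t_s / 3600
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t_h, y = .data$z_mm)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$concentration_uM)) +
    ggplot2::scale_fill_viridis_c(name = expression("C (" * mu * "M)")) +
    ggplot2::labs(x = "time (h)", y = "z (mm, 0 = foramen magnum)") +
    ggplot2::theme_minimal()
  if (length(contours) && max(df$concentration_uM) > min(contours)) {
    p <- p + ggplot2::geom_contour(
      ggplot2::aes(z = .data$concentration_uM),
      breaks = contours, colour = "white", linewidth = 0.2)
  }
  p
}

#' @rdname autoplot.concentration_field
#' @export
autoplot.spatiotemporal_map <- autoplot.concentration_field

#' Plot a volume profile
#'
#' @param object A [volume_profile()].
#' @param ... Unused.
#' @return A ggplot of per-slice volume against z.
#' @export
autoplot.volume_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z_mm, y = .data$volume_ml)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "z (mm, 0 = foramen magnum)", y = "slice volume (ml)") +
    ggplot2::theme_minimal()
}

#' Plot a flow waveform
#'
#' @param object A `flow_waveform`.
#' @param ... Unused.
#' @return A ggplot of flow rate against time.
#' @export
autoplot.flow_waveform <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t_s, y = .data$q_ml_per_s)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "flow rate (ml/s)") +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot
#'
#' @param object A `bland_altman`.
#' @param ... Unused.
#' @return A ggplot: per-point differences against the repetition mean, with
#'   the mean difference and limits of agreement.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$differences,
                  ggplot2::aes(x = .data$mean_value, y = .data$difference,
                               colour = factor(.data$repetition))) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = object$mean_difference) +
    ggplot2::geom_hline(yintercept = c(object$lower_limit, object$upper_limit),
                        linetype = "dashed") +
    ggplot2::labs(x = "mean of repetitions", y = "difference from mean",
                  colour = "repetition") +
    ggplot2::theme_minimal()
}

#' Plot the repetition standard-deviation map
#'
#' @param x A `repeat_stats`.
#' @param what `"sd"`, `"ci"` or `"mean"`.
#' @return A ggplot heatmap.
#' @export
plot_sd_map <- function(x, what = c("sd", "ci", "mean")) {
  what <- match.arg(what)
  df <- tidy(x)
  df$t_h <- df$t_s / 3600
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_h, y = .data$z_mm)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data[[what]])) +
    ggplot2::scale_fill_viridis_c(name = paste0(what, " (uM)")) +
    ggplot2::labs(x = "time (h)", y = "z (mm)") +
    ggplot2::theme_minimal()
}
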