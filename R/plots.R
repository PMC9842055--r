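# ggplot2 displays for the main result types.

#' @export
autoplot.spl_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$dba)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = "Time (s)", y = "A-weighted SPL (dBA)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pressure_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$pressure_cmh2o)) +
    ggplot2::geom_line(colour = "#636363") +
    ggplot2::labs(x = "Time (s)", y = expression(P[airway] ~ (cmH[2] * O))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.leak_spectrogram <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$time_s, .data$frequency_hz,
                               fill = .data$power_db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "dB re FS") +
    ggplot2::labs(x = "Time (s)", y = "Frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.power_spectrum <- function(object, bands = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$frequency_hz, .data$power_db)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = "Frequency (Hz)", y = "Power (dB re FS)") +
    ggplot2::theme_minimal()
  if (!is.null(bands) && nrow(bands) > 0) {
    p <- p +
      ggplot2::geom_point(data = bands,
                          ggplot2::aes(.data$center_hz, .data$peak_power_db),
                          colour = "#d95f02", size = 2) +
      ggplot2::geom_text(data = bands,
                         ggplot2::aes(.data$center_hz, .data$peak_power_db,
                                      label = .data$label),
                         vjust = -0.8, size = 3)
  }
  p
}

#' @export
autoplot.intensity_matrix <- function(object, ...) {
  df <- as_tibble(object)
  fill <- if (all(is.na(df$normalized))) "raw_dba" else "normalized"
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data[[fill]])) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data[[fill]])),
                       colour = "white", size = 3) +
    ggplot2::scale_y_reverse() +   # origin upper-left, y downward
    ggplot2::scale_fill_viridis_c(name = if (fill == "normalized")
      "Normalized\nintensity" else "dBA") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Column", y = "Row") +
    ggplot2::theme_minimal()
}
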