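#' Plot a raster view
#'
#' @param object A `raster_view` from [order_channels()].
#' @param ... Unused.
#' @return A ggplot: one row per channel (top row first), a mark per spike.
#' @export
autoplot.raster_view <- function(object, ...) {
  df <- object$spikes
  nch <- length(object$channels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = nch + 1 - .data$row)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::scale_y_continuous(breaks = seq_len(nch),
                                labels = rev(object$channels)) +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = sprintf("raster (%s ordering)", object$scheme)) +
    ggplot2::theme_minimal()
}

#' Plot a downsampled trace
#'
#' @param object A tibble from [minmax_downsample()].
#' @param ... Unused.
#' @export
plot_downsampled <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "voltage (µV)") +
    ggplot2::theme_minimal()
}

#' Plot a latency map
#'
#' @param object A `latency_map` from [latency_map()].
#' @param ... Unused.
#' @return A ggplot tile map mirroring the array geometry; colour encodes
#'   the propagation latency in ms, grey cells carry no propagation signal.
#' @export
autoplot.latency_map <- function(object, ...) {
  df <- as_tibble.latency_map(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = -.data$row,
                                   fill = .data$latency_ms)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$electrode), size = 2.5) +
    ggplot2::scale_fill_viridis_c(na.value = "grey90",
                                  name = "latency (ms)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Plot the mean traces of a propagation result on the array grid
#'
#' @param object An averaged [propagation_result].
#' @param layout A [mea_layout] for facet placement.
#' @param ... Unused.
#' @export
autoplot.propagation_result <- function(object, layout = NULL, ...) {
  df <- as_tibble.propagation_result(object)
  facet <- ggplot2::facet_wrap(ggplot2::vars(.data$electrode))
  if (!is.null(layout)) {
    pos <- as_tibble.mea_layout(layout)
    df <- dplyr::inner_join(df, pos, by = "electrode")
    facet <- ggplot2::facet_grid(ggplot2::vars(.data$row),
                                 ggplot2::vars(.data$column))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$latency_ms,
                                   y = .data$mean_uv)) +
    ggplot2::geom_line(linewidth = 0.3) +
    facet +
    ggplot2::labs(x = "latency (ms)", y = "mean voltage (µV)") +
    ggplot2::theme_minimal()
}
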