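#' Tidy a propagation result
#'
#' @param x A [propagation_result].
#' @param ... Unused.
#' @return One row per channel: electrode, event count, peak latency (ms),
#'   jitter (ms), mean-trace peak (uV, signed), above-threshold flag and
#'   classification (`NA` columns where the corresponding stage has not run).
#' @export
tidy.propagation_result <- function(x, ...) {
  purrr::map_dfr(x$ensembles, function(en) {
    tibble::tibble(
      electrode = en$electrode,
      n_events = nrow(en$windows),
      peak_latency_ms = en$peak_latency %||% NA_real_,
      jitter_ms = en$jitter %||% NA_real_,
      peak_uv = if (is.null(en$mean_trace)) NA_real_
                else en$mean_trace[which.max(abs(en$mean_trace))],
      above_threshold = en$above_threshold %||% NA,
      classification = en$classification %||% NA_character_)
  })
}

#' Summarize a propagation result
#'
#' @param x A [propagation_result].
#' @param ... Unused.
#' @return A one-row tibble: channel count, aligned event count, dropped
#'   events, and per-class channel counts.
#' @export
glance.propagation_result <- function(x, ...) {
  cls <- vapply(x$ensembles, function(en) en$classification %||% NA_character_,
                character(1))
  tibble::tibble(
    n_channels = length(x$ensembles),
    n_events = x$n_events,
    n_dropped = x$n_dropped,
    n_propagation = sum(cls == "propagation", na.rm = TRUE),
    n_coupled = sum(cls == "coupled", na.rm = TRUE),
    n_unlocked = sum(cls == "unlocked", na.rm = TRUE))
}

#' Mean traces of a propagation result as a long tibble
#'
#' @param x A [propagation_result] (averaged).
#' @param ... Unused.
#' @return Long tibble with `electrode`, `latency_ms` (relative to the
#'   window center) and `mean_uv`.
#' @export
as_tibble.propagation_result <- function(x, ...) {
  fs <- x$sampling_rate
  purrr::map_dfr(x$ensembles, function(en) {
    if (is.null(en$mean_trace)) return(tibble::tibble())
    tibble::tibble(
      electrode = en$electrode,
      latency_ms = (seq_along(en$mean_trace) - x$center) / fs * 1000,
      mean_uv = en$mean_trace)
  })
}

#' @export
as_tibble.latency_map <- function(x, ...) {
  lay <- attr(x, "layout")
  tb <- as_tibble.mea_layout(lay)
  tb$latency_ms <- x[cbind(tb$row + 1L, tb$column + 1L)]
  tb
}
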