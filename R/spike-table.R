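#' Spike event tables
#'
#' Spike events are kept in plain tibbles with columns `electrode` (label),
#' `time` (seconds), `amplitude` (signed peak, microvolts), `unit` (integer
#' cluster id, -1 = unsorted/noise) and `redundant` (logical; set only by
#' [tag_redundant()]). Tables are globally sorted by time, ties broken by
#' electrode label so the ordering is stable.
#'
#' @param electrode Character vector of electrode labels.
#' @param time Numeric vector of spike times in seconds (>= 0).
#' @param amplitude Numeric vector of signed peak amplitudes in microvolts.
#' @param unit Integer cluster ids; -1 marks unsorted/noise events.
#' @param redundant Logical; whether the event is a redundant co-detection.
#' @return A tibble sorted by `time` then `electrode`.
#' @export
spike_table <- function(electrode = character(), time = numeric(),
                        amplitude = numeric(),
                        unit = rep(-1L, length(time)),
                        redundant = rep(FALSE, length(time))) {
  if (length(time) && any(time < 0))
    rlang::abort("spike times must be >= 0",
                 class = "spikegrid_validation_error")
  tbl <- tibble::tibble(electrode = as.character(electrode),
                        time = as.numeric(time),
                        amplitude = as.numeric(amplitude),
                        unit = as.integer(unit),
                        redundant = as.logical(redundant))
  dplyr::arrange(tbl, .data$time, .data$electrode)
}

#' Read and write spike tables as CSV
#'
#' The CSV dialect is a header `electrode,time,amplitude,unit`, comma
#' separated, "." decimal, times in seconds. The `unit` column is optional on
#' read (missing implies -1, unsorted); the `redundant` column is written only
#' when any flag is set and restored on read when present.
#'
#' @param path Path to a CSV file.
#' @return `read_spikes()`: a [spike_table] tibble sorted by time.
#' @export
read_spikes <- function(path) {
  if (!file.exists(path))
    rlang::abort(sprintf("no such file: %s", path),
                 class = "spikegrid_io_error")
  # parsing problems are surfaced as classed errors below, not readr warnings
  tbl <- suppressWarnings(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(
                      electrode = readr::col_character(),
                      .default = readr::col_double())))
  required <- c("electrode", "time", "amplitude")
  missing <- setdiff(required, names(tbl))
  if (length(missing))
    rlang::abort(sprintf("spike CSV is missing column(s): %s",
                         paste(missing, collapse = ", ")),
                 class = "spikegrid_format_error")
  probs <- readr::problems(tbl)
  if (nrow(probs))
    rlang::abort(sprintf("cannot parse spike CSV %s: line %d: expected %s",
                         path, probs$row[1] + 1L, probs$expected[1]),
                 class = "spikegrid_format_error")
  if (nrow(tbl) && (anyNA(tbl$time) || anyNA(tbl$amplitude)))
    rlang::abort(sprintf("non-numeric time/amplitude in %s (first bad line %d)",
                         path,
                         which(is.na(tbl$time) | is.na(tbl$amplitude))[1] + 1L),
                 class = "spikegrid_format_error")
  spike_table(
    electrode = tbl$electrode, time = tbl$time, amplitude = tbl$amplitude,
    unit = if ("unit" %in% names(tbl)) tbl$unit else rep(-1L, nrow(tbl)),
    redundant = if ("redundant" %in% names(tbl)) tbl$redundant > 0
                else rep(FALSE, nrow(tbl)))
}

#' @rdname read_spikes
#' @param table A [spike_table] tibble.
#' @return `write_spikes()`: `path`, invisibly.
#' @export
write_spikes <- function(table, path) {
  out <- dplyr::select(table, dplyr::any_of(
    c("electrode", "time", "amplitude", "unit", "redundant")))
  if ("redundant" %in% names(out) && !any(out$redundant))
    out$redundant <- NULL
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
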