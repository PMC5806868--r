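#' Propagation analysis configuration
#'
#' Parameters for detecting stereotyped coincident spiking, spike-triggered
#' averaging, and separating axonal propagation from synaptic coupling.
#' Propagation of one action potential along an axon shows up as
#' sub-millisecond inter-electrode delays with very little jitter; spiking of
#' a synaptically coupled partner follows at 1-10 ms with visibly more
#' jitter.
#'
#' @param coincidence_window Two spikes on different electrodes within this
#'   many ms count as coincident (default 0.7).
#' @param extraction_window Length of the window cut around each reference
#'   spike, ms, centered (default 20).
#' @param min_repeats Minimum number of coincidences for a channel pair to
#'   count as stereotyped (default 30).
#' @param propagation_max_delay Largest mean latency (ms, absolute) still
#'   attributed to axonal propagation (default 1).
#' @param coupled_delay_range Mean-latency range (ms, absolute) expected for
#'   synaptically coupled partners (default 1-10).
#' @param propagation_max_jitter Largest per-event latency s.d. (ms) still
#'   attributed to propagation (default 0.3).
#' @param locked_peak_criterion A channel counts as time-locked when its
#'   mean-trace peak exceeds this multiple of `sigma / sqrt(N)`, the residual
#'   noise level after averaging N windows (default 4).
#' @return An object of class `propagation_config`.
#' @export
propagation_config <- function(coincidence_window = 0.7,
                               extraction_window = 20,
                               min_repeats = 30,
                               propagation_max_delay = 1.0,
                               coupled_delay_range = c(1.0, 10.0),
                               propagation_max_jitter = 0.3,
                               locked_peak_criterion = 4) {
  if (coincidence_window <= 0 || extraction_window <= 0 || min_repeats < 2)
    rlang::abort("invalid propagation configuration",
                 class = "spikegrid_parameter_error")
  structure(list(coincidence_window = coincidence_window,
                 extraction_window = extraction_window,
                 min_repeats = min_repeats,
                 propagation_max_delay = propagation_max_delay,
                 coupled_delay_range = coupled_delay_range,
                 propagation_max_jitter = propagation_max_jitter,
                 locked_peak_criterion = locked_peak_criterion),
            class = "propagation_config")
}

# maximum one-to-one matching of two sorted time vectors within w seconds
match_times <- function(ta, tb, w) {
  ia <- integer(0)
  i <- 1L
  j <- 1L
  na <- length(ta)
  nb <- length(tb)
  while (i <= na && j <= nb) {
    d <- ta[i] - tb[j]
    if (abs(d) <= w) {
      ia <- c(ia, i)
      i <- i + 1L
      j <- j + 1L
    } else if (d < 0) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  ia
}

#' Find stereotyped coincident channel pairs
#'
#' For every ordered pair of electrodes, counts how many spikes on the first
#' can be matched one-to-one to a spike on the second within the coincidence
#' window (nearest-neighbour matching, each spike used at most once). Pairs
#' reaching `min_repeats` are returned in descending count order; both
#' orderings of a pair appear, with equal counts.
#'
#' @param table A [spike_table].
#' @param cfg A [propagation_config].
#' @return A tibble with columns `electrode_a`, `electrode_b`, `count`.
#' @export
find_coincident_pairs <- function(table, cfg = propagation_config()) {
  chans <- sort(unique(table$electrode))
  w <- cfg$coincidence_window / 1000
  times <- purrr::map(chans, ~ sort(table$time[table$electrode == .x]))
  names(times) <- chans
  rows <- list()
  if (length(chans) >= 2) {
    combs <- utils::combn(chans, 2)
    for (k in seq_len(ncol(combs))) {
      a <- combs[1, k]
      b <- combs[2, k]
      cnt <- length(match_times(times[[a]], times[[b]], w))
      if (cnt >= cfg$min_repeats)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          electrode_a = c(a, b), electrode_b = c(b, a), count = cnt)
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows)
  else tibble::tibble(electrode_a = character(), electrode_b = character(),
                      count = integer())
  dplyr::arrange(out, dplyr::desc(.data$count), .data$electrode_a)
}

#' Reference spike times for averaging
#'
#' The reference for spike-triggered averaging is either a coincident pair
#' (times are taken from the first-listed channel, restricted to events with
#' a partner on the second within the coincidence window) or a single
#' channel, optionally restricted to one sorted unit.
#'
#' @param table A [spike_table].
#' @param reference A single electrode label, or a length-2 character vector
#'   `c(reference_channel, test_channel)`.
#' @param unit Optional unit id to filter on (single-channel reference).
#' @param cfg A [propagation_config].
#' @return Numeric vector of reference times, seconds.
#' @export
reference_times <- function(table, reference, unit = NULL,
                            cfg = propagation_config()) {
  chans <- unique(table$electrode)
  missing <- setdiff(reference, chans)
  if (length(missing))
    rlang::abort(sprintf("reference electrode(s) not in table: %s",
                         paste(missing, collapse = ", ")),
                 class = "spikegrid_lookup_error")
  if (length(reference) == 2) {
    ta <- sort(table$time[table$electrode == reference[1]])
    tb <- sort(table$time[table$electrode == reference[2]])
    out <- ta[match_times(ta, tb, cfg$coincidence_window / 1000)]
    if (!length(out))
      rlang::warn(sprintf("no coincidences between %s and %s",
                          reference[1], reference[2]))
    out
  } else {
    sel <- table$electrode == reference
    if (!is.null(unit)) sel <- sel & table$unit == unit
    sort(table$time[sel])
  }
}

#' Extract reference-aligned windows on every channel
#'
#' Cuts a centered window of `extraction_window` ms from every channel of the
#' recording at each reference time. Any event whose window would cross a
#' record boundary is dropped from all channels, so every channel ensemble
#' holds the same N events and their averages are comparable.
#'
#' @param rec An [analog_recording].
#' @param times Reference spike times, seconds.
#' @param cfg A [propagation_config].
#' @param reference Optional label (or pair) recorded on the result.
#' @return An object of class `propagation_result` whose `ensembles` hold the
#'   raw aligned windows; statistics are filled by [average_ensembles()] and
#'   [classify_channels()].
#' @export
extract_aligned <- function(rec, times, cfg = propagation_config(),
                            reference = NULL) {
  fs <- rec$sampling_rate
  w <- round(cfg$extraction_window / 1000 * fs) + 1L
  pre <- (w - 1L) %/% 2L
  post <- w - 1L - pre
  idx <- round((times - rec$start_time) * fs) + 1L
  keep <- idx - pre >= 1L & idx + post <= ncol(rec$data)
  idx <- idx[keep]
  if (!length(idx))
    rlang::abort("no reference event has a full window on all channels",
                 class = "spikegrid_input_error")
  ensembles <- purrr::map(seq_along(rec$channel_ids), function(ch) {
    windows <- matrix(0, nrow = length(idx), ncol = w)
    for (j in seq_along(idx))
      windows[j, ] <- rec$data[ch, (idx[j] - pre):(idx[j] + post)]
    list(electrode = rec$channel_ids[ch], windows = windows,
         mean_trace = NULL, peak_latency = NULL, jitter = NULL,
         above_threshold = NULL, classification = NULL)
  })
  names(ensembles) <- rec$channel_ids
  structure(list(reference = reference,
                 reference_times = (idx - 1L) / fs + rec$start_time,
                 ensembles = ensembles, sampling_rate = fs,
                 n_events = length(idx), n_dropped = sum(!keep),
                 center = pre + 1L),
            class = "propagation_result")
}

#' @export
print.propagation_result <- function(x, ...) {
  cat(sprintf(
    "<propagation_result: %d channels x %d aligned events (%d samples/window)>\n",
    length(x$ensembles), x$n_events, ncol(x$ensembles[[1]]$windows)))
  if (!is.null(x$ensembles[[1]]$classification)) {
    cls <- vapply(x$ensembles, `[[`, "", "classification")
    cat("  ", paste(sprintf("%s: %d", names(table(cls)), table(cls)),
                    collapse = ", "), "\n")
  }
  invisible(x)
}

#' Average aligned ensembles
#'
#' Fills each channel ensemble's mean trace (per-sample arithmetic mean over
#' events), peak latency (time of the mean trace's extremum relative to the
#' window center, ms) and jitter (s.d. of the per-event extremum latency,
#' searched within +/- 1 ms of the mean-trace peak so the statistic stays
#' well defined at low signal-to-noise). Averaging N windows reduces
#' uncorrelated noise by sqrt(N), which is what recovers sub-threshold
#' time-locked waveforms.
#'
#' @param result A [propagation_result] from [extract_aligned()].
#' @return The result with `mean_trace`, `peak_latency` and `jitter` filled.
#' @export
average_ensembles <- function(result) {
  fs <- result$sampling_rate
  center <- result$center
  half_ms <- round(0.001 * fs)
  result$ensembles <- purrr::map(result$ensembles, function(en) {
    mt <- colMeans(en$windows)
    ipk <- which.max(abs(mt))
    sign_neg <- mt[ipk] < 0
    span <- max(1L, ipk - half_ms):min(length(mt), ipk + half_ms)
    per_event <- apply(en$windows[, span, drop = FALSE], 1, function(row)
      span[if (sign_neg) which.min(row) else which.max(row)])
    en$mean_trace <- mt
    en$peak_latency <- (ipk - center) / fs * 1000
    en$jitter <- if (length(per_event) > 1)
      stats::sd((per_event - center) / fs * 1000) else 0
    en
  })
  result
}

#' Classify channels as propagation, coupled or unlocked
#'
#' A channel whose mean-trace peak stays below
#' `locked_peak_criterion * sigma / sqrt(N)` carries no time-locked signal
#' (`"unlocked"`). Otherwise it is `"propagation"` when its latency is within
#' `propagation_max_delay` of the reference and its jitter at most
#' `propagation_max_jitter` (one action potential travelling along an axon),
#' and `"coupled"` when the latency falls in `coupled_delay_range` or the
#' jitter is larger (pre-/post-synaptic partner spiking). A locked channel
#' matching neither pattern is left `"unlocked"`. `above_threshold` records
#' whether the mean-trace peak magnitude reaches the channel's spike
#' detection threshold (`threshold_multiplier * sigma`).
#'
#' @param result An averaged [propagation_result].
#' @param cfg A [propagation_config].
#' @param sigma Named numeric vector of per-channel noise s.d. (uV).
#' @param threshold_multiplier Detection threshold multiple of sigma.
#' @return The result with `classification` and `above_threshold` filled.
#' @export
classify_channels <- function(result, cfg = propagation_config(), sigma,
                              threshold_multiplier = 6) {
  n <- result$n_events
  result$ensembles <- purrr::map(result$ensembles, function(en) {
    if (is.null(en$mean_trace))
      rlang::abort("run average_ensembles() before classify_channels()",
                   class = "spikegrid_input_error")
    s <- sigma[[en$electrode]]
    peak <- max(abs(en$mean_trace))
    en$above_threshold <- peak >= threshold_multiplier * s
    lat <- abs(en$peak_latency)
    en$classification <-
      if (peak < cfg$locked_peak_criterion * s / sqrt(n)) "unlocked"
      else if (lat <= cfg$propagation_max_delay &&
               en$jitter <= cfg$propagation_max_jitter) "propagation"
      else if ((lat >= cfg$coupled_delay_range[1] &&
                lat <= cfg$coupled_delay_range[2]) ||
               en$jitter > cfg$propagation_max_jitter) "coupled"
      else "unlocked"
    en
  })
  result
}

#' Map propagation latencies onto the array geometry
#'
#' @param result A classified [propagation_result].
#' @param layout A [mea_layout].
#' @return A `latency_map`: rows x columns numeric matrix of mean peak
#'   latencies (ms) at propagation-classified electrodes, `NA` elsewhere.
#' @export
latency_map <- function(result, layout) {
  m <- matrix(NA_real_, nrow = layout$rows, ncol = layout$columns)
  any_prop <- FALSE
  for (en in result$ensembles) {
    if (is.null(en$classification))
      rlang::abort("run classify_channels() before latency_map()",
                   class = "spikegrid_input_error")
    if (identical(en$classification, "propagation")) {
      co <- coordinates_for_electrode(layout, en$electrode)
      m[co["row"] + 1L, co["column"] + 1L] <- en$peak_latency
      any_prop <- TRUE
    }
  }
  if (!any_prop)
    rlang::warn("no propagation-classified channels; latency map is empty")
  structure(m, class = c("latency_map", "matrix"), layout = layout)
}

#' Full propagation analysis pipeline
#'
#' Convenience wrapper: reference times, aligned extraction, averaging and
#' classification in one call.
#'
#' @inheritParams extract_aligned
#' @param table A [spike_table] used to derive reference times.
#' @param reference Electrode label or pair; see [reference_times()].
#' @param unit Optional unit filter for a single-channel reference.
#' @param sigma Per-channel noise s.d.; estimated from `rec` when omitted.
#' @param threshold_multiplier Detection threshold multiple of sigma.
#' @return A classified [propagation_result].
#' @export
propagation_analysis <- function(rec, table, reference, unit = NULL,
                                 cfg = propagation_config(), sigma = NULL,
                                 threshold_multiplier = 6) {
  if (is.null(sigma)) {
    sigma <- apply(rec$data, 1, estimate_noise)
    names(sigma) <- rec$channel_ids
  }
  times <- reference_times(table, reference, unit = unit, cfg = cfg)
  result <- extract_aligned(rec, times, cfg, reference = reference)
  result <- average_ensembles(result)
  classify_channels(result, cfg, sigma, threshold_multiplier)
}
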