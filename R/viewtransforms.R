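#' Extrema-preserving min/max downsampling
#'
#' Downsampling a long spike-bearing trace for display by taking every n-th
#' sample is likely to miss the brief spikes entirely. Instead the samples
#' are binned into `n_p` near-equal bins (one per display pixel) and each
#' bin's minimum and maximum are emitted, in the temporal order in which they
#' occur inside the bin, so a plotted line strip never loses an extremum and
#' never draws a phantom zig-zag. When `n_p` is at least the sample count the
#' raw samples are returned unchanged.
#'
#' @param signal Numeric vector of samples, microvolts.
#' @param sampling_rate Hz.
#' @param n_p Number of display pixels (bins), >= 1.
#' @param start_time Time of the first sample, seconds.
#' @return A tibble with columns `time` (s) and `value` (uV); at most
#'   `2 * n_p` rows, and the global min and max of `signal` always present.
#' @export
minmax_downsample <- function(signal, sampling_rate, n_p, start_time = 0) {
  if (n_p < 1)
    rlang::abort("n_p must be >= 1", class = "spikegrid_parameter_error")
  n <- length(signal)
  times <- start_time + (seq_len(n) - 1) / sampling_rate
  if (n_p >= n)
    return(tibble::tibble(time = times, value = as.numeric(signal)))
  # near-equal integer partition: the first (n mod n_p) bins get 1 extra
  sizes <- rep(n %/% n_p, n_p)
  extra <- n %% n_p
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-n_p] + 1L)
  out_t <- numeric(2L * n_p)
  out_v <- numeric(2L * n_p)
  for (b in seq_len(n_p)) {
    span <- starts[b]:ends[b]
    i_min <- span[which.min(signal[span])]
    i_max <- span[which.max(signal[span])]
    first <- min(i_min, i_max)
    second <- max(i_min, i_max)
    out_t[2L * b - 1L] <- times[first]
    out_v[2L * b - 1L] <- signal[first]
    out_t[2L * b] <- times[second]
    out_v[2L * b] <- signal[second]
  }
  tibble::tibble(time = out_t, value = out_v)
}

#' Raster display resolution
#'
#' How much recording time one horizontal pixel of a raster plot spans: a
#' 3-minute record on a 1400-pixel display is ~130 ms/px, so spikes inside a
#' burst merge into single marks. Reported to 2 significant figures, the
#' precision at which such a resolution is meaningfully quoted.
#'
#' @param span Displayed time span, seconds.
#' @param pixels Horizontal pixel count, >= 1.
#' @return Milliseconds of recording per pixel, 2 significant figures.
#' @export
pixel_duration <- function(span, pixels) {
  if (pixels < 1 || span <= 0)
    rlang::abort("need span > 0 and pixels >= 1",
                 class = "spikegrid_parameter_error")
  signif(span * 1000 / pixels, 2)
}

#' Order channels for a raster view
#'
#' Builds a `raster_view`: the channel ordering (top row first) plus the
#' per-channel spike times. Schemes: `"activity"` sorts by descending spike
#' count; `"latency"` by ascending time of the first spike at or after `t0`
#' (channels silent after `t0` go last); `"fixed"` uses `fixed_order`. All
#' ties, including silent channels, break by lexicographic label order.
#'
#' @param table A [spike_table].
#' @param scheme `"activity"`, `"latency"` or `"fixed"`.
#' @param t0 Reference time (s) for the latency scheme.
#' @param fixed_order Character vector: a permutation of the table's
#'   channels, for the fixed scheme.
#' @return An object of class `raster_view`: list with `channels` (ordered,
#'   top to bottom), `spikes` (the table with a `row` position column) and
#'   `scheme`.
#' @export
order_channels <- function(table, scheme = c("activity", "latency", "fixed"),
                           t0 = NULL, fixed_order = NULL) {
  scheme <- tryCatch(match.arg(scheme), error = function(e)
    rlang::abort(sprintf("unknown ordering scheme '%s'", scheme[1]),
                 class = "spikegrid_parameter_error"))
  chans <- sort(unique(table$electrode))
  ordered <- switch(scheme,
    activity = {
      counts <- table(factor(table$electrode, levels = chans))
      chans[order(-as.integer(counts), chans)]
    },
    latency = {
      if (is.null(t0))
        rlang::abort("latency ordering needs t0",
                     class = "spikegrid_parameter_error")
      first <- vapply(chans, function(ch) {
        t <- table$time[table$electrode == ch & table$time >= t0]
        if (length(t)) min(t) else Inf
      }, numeric(1))
      chans[order(first, chans)]
    },
    fixed = {
      if (is.null(fixed_order))
        rlang::abort("fixed ordering needs fixed_order",
                     class = "spikegrid_parameter_error")
      if (!setequal(fixed_order, chans) || anyDuplicated(fixed_order))
        rlang::abort("fixed_order must be a permutation of the table's channels",
                     class = "spikegrid_parameter_error")
      as.character(fixed_order)
    })
  spikes <- dplyr::mutate(
    table, row = match(.data$electrode, ordered))
  structure(list(channels = ordered, spikes = spikes, scheme = scheme),
            class = "raster_view")
}

#' @export
print.raster_view <- function(x, ...) {
  cat(sprintf("<raster_view: %d channels, %d spikes, scheme '%s'>\n",
              length(x$channels), nrow(x$spikes), x$scheme))
  invisible(x)
}

#' Bin spikes into spatiotemporal frames
#'
#' The flashing-spike view: recording time in `[t_start, t_end)` is cut into
#' frames of `playback_factor / frame_rate` seconds (a playback factor of 1
#' is real time; 1/1600 stretches 25 us of recording over each displayed
#' frame at 25 fps), and each spike increments the intensity of its
#' electrode's grid cell in the frame containing its time. With
#' `decay_frames > 0` each flash additionally decays exponentially over
#' subsequent frames for display smoothness; the onset counts are kept
#' separately so total onsets always equal the number of spikes in the
#' window.
#'
#' @param table A [spike_table]; every electrode must be in `layout`.
#' @param layout A [mea_layout].
#' @param t_start,t_end Half-open recording-time window, seconds.
#' @param frame_rate Display frames per second.
#' @param playback_factor Recording seconds per displayed second, in
#'   `[1/1600, 1]`.
#' @param decay_frames Exponential decay time constant in frames (0 = flash
#'   lives only in its onset frame).
#' @return An object of class `frame_sequence`: list with `frames` (list of
#'   rows x columns intensity matrices), `onsets` (same shape, onset counts
#'   only), `frame_span` (s), `playback_factor`, `t_start`.
#' @export
spikes_to_frames <- function(table, layout, t_start, t_end, frame_rate = 25,
                             playback_factor = 1, decay_frames = 0) {
  if (t_start >= t_end)
    rlang::abort("need t_start < t_end", class = "spikegrid_parameter_error")
  if (playback_factor < 1 / 1600 || playback_factor > 1)
    rlang::abort("playback_factor must be in [1/1600, 1]",
                 class = "spikegrid_parameter_error")
  frame_span <- playback_factor / frame_rate
  n_frames <- ceiling((t_end - t_start) / frame_span)
  empty <- matrix(0, nrow = layout$rows, ncol = layout$columns)
  onsets <- replicate(n_frames, empty, simplify = FALSE)
  sel <- table$time >= t_start & table$time < t_end
  for (i in which(sel)) {
    co <- coordinates_for_electrode(layout, table$electrode[i])
    f <- floor((table$time[i] - t_start) / frame_span) + 1L
    onsets[[f]][co["row"] + 1L, co["column"] + 1L] <-
      onsets[[f]][co["row"] + 1L, co["column"] + 1L] + 1
  }
  frames <- onsets
  if (decay_frames > 0 && n_frames > 1) {
    k <- exp(-1 / decay_frames)
    for (f in 2:n_frames) frames[[f]] <- frames[[f]] + k * frames[[f - 1L]]
  }
  structure(list(frames = frames, onsets = onsets, frame_span = frame_span,
                 playback_factor = playback_factor, t_start = t_start),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf(
    "<frame_sequence: %d frames of %g s recording time each (playback 1/%g)>\n",
    length(x$frames), x$frame_span, 1 / x$playback_factor))
  invisible(x)
}
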