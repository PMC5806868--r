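#' Biphasic extracellular spike template
#'
#' Builds an idealized extracellular action potential: a sharp negative trough
#' followed by a broader, shallower positive after-peak. Each lobe is a raised
#' cosine (Hann) bump; the lobes have disjoint support, so the trough minimum
#' and after-peak maximum equal their nominal amplitudes exactly, and with the
#' default geometry the positive lobe's area balances the trough's, giving a
#' near-zero net integral (biphasic balance). Total support is capped at 4 ms,
#' the upper end of reported transmembrane action-potential durations.
#'
#' @param sampling_rate Hz.
#' @param trough_amplitude Trough depth in microvolts; must be negative.
#' @param trough_width Full width at half maximum of the trough lobe, ms
#'   (within 0.2-4 ms).
#' @param after_peak_fraction After-peak height as a fraction of `|trough|`.
#' @return Numeric vector of template samples (microvolts), zero at both ends,
#'   with attribute `center` giving the 1-based index of the trough sample.
#' @export
biphasic_template <- function(sampling_rate, trough_amplitude = -80,
                              trough_width = 0.4, after_peak_fraction = 0.3) {
  if (trough_amplitude >= 0)
    rlang::abort("trough_amplitude must be negative (extracellular trough)",
                 class = "spikegrid_parameter_error")
  if (trough_width < 0.2 || trough_width > 4)
    rlang::abort("trough_width must be in [0.2, 4] ms",
                 class = "spikegrid_parameter_error")
  a <- abs(trough_amplitude)
  w1 <- 2 * trough_width / 1000                    # Hann support; FWHM = w1/2
  w2 <- min(w1 / after_peak_fraction, 0.004 - w1)  # area balance, <= 4 ms
  if (w2 <= 0)
    rlang::abort("trough too wide for a 4 ms biphasic template",
                 class = "spikegrid_parameter_error")
  dt <- 1 / sampling_rate
  # after-peak center lands exactly on a sample so max is exact
  offset <- ceiling((w1 + w2) / 2 / dt) * dt
  n_pre <- ceiling(w1 / 2 / dt)
  n_post <- ceiling((offset + w2 / 2) / dt)
  t <- (-n_pre:n_post) * dt
  hann <- function(t, c, w) ifelse(abs(t - c) <= w / 2,
                                   cos(pi * (t - c) / w)^2, 0)
  y <- -a * hann(t, 0, w1) + after_peak_fraction * a * hann(t, offset, w2)
  structure(y, center = n_pre + 1L)
}

#' Synthetic unit specification
#'
#' Describes one simulated neuron contributing events to a synthetic
#' recording.
#'
#' @param kind `"simple"` (one electrode), `"propagating"` (an axonal path:
#'   one action potential appears on several electrodes at fixed,
#'   non-decreasing latencies) or `"coupled"` (a synaptically driven follower
#'   that fires after a parent unit with a longer, jittered delay).
#' @param electrodes Electrode labels the unit appears on (in path order for
#'   propagating units).
#' @param latencies_ms Per-electrode latency of the spike relative to the
#'   unit's event time, ms; non-decreasing for propagating units.
#' @param amplitudes_uv Per-electrode trough amplitude, microvolts (negative).
#' @param firing Firing model: `list(type = "poisson", rate = Hz)`, or
#'   `list(type = "fixed_n", n = count, min_isi_ms = spacing)` drawing exactly
#'   `n` event times uniformly with a minimum inter-event interval, or
#'   `list(type = "burst", rate = bursts/s, size = events, interval_ms = gap)`.
#' @param jitter_ms Per-event, per-electrode latency jitter s.d., ms.
#' @param parent For coupled units: index of the parent unit in the config's
#'   unit list.
#' @param delay_ms,delay_sd_ms For coupled units: mean and s.d. of the
#'   follow delay (normal, truncated at 0), ms.
#' @param follow_prob For coupled units: probability of following each parent
#'   event.
#' @param trough_width_ms,after_peak_fraction Template shape parameters; see
#'   [biphasic_template()].
#' @return An object of class `unit_spec`.
#' @export
unit_spec <- function(kind = c("simple", "propagating", "coupled"),
                      electrodes, latencies_ms = 0, amplitudes_uv,
                      firing = list(type = "poisson", rate = 1),
                      jitter_ms = 0, parent = NULL,
                      delay_ms = 3, delay_sd_ms = 0.8, follow_prob = 1,
                      trough_width_ms = 0.4, after_peak_fraction = 0.3) {
  kind <- match.arg(kind)
  latencies_ms <- rep_len(latencies_ms, length(electrodes))
  amplitudes_uv <- rep_len(amplitudes_uv, length(electrodes))
  if (any(amplitudes_uv >= 0))
    rlang::abort("amplitudes_uv must be negative",
                 class = "spikegrid_validation_error")
  if (kind == "propagating" && is.unsorted(latencies_ms))
    rlang::abort("propagating latencies must be non-decreasing along the path",
                 class = "spikegrid_validation_error")
  if (kind == "coupled" && is.null(parent))
    rlang::abort("coupled units need a parent",
                 class = "spikegrid_validation_error")
  structure(list(kind = kind, electrodes = as.character(electrodes),
                 latencies_ms = latencies_ms, amplitudes_uv = amplitudes_uv,
                 firing = firing, jitter_ms = jitter_ms, parent = parent,
                 delay_ms = delay_ms, delay_sd_ms = delay_sd_ms,
                 follow_prob = follow_prob,
                 trough_width_ms = trough_width_ms,
                 after_peak_fraction = after_peak_fraction),
            class = "unit_spec")
}

#' Synthetic recording configuration
#'
#' @param layout A [mea_layout] naming the channels to simulate.
#' @param duration Recording length, seconds.
#' @param sampling_rate Hz (default 20000, the regime of commercial
#'   120-electrode MEA systems).
#' @param noise_sigma Gaussian background noise s.d., microvolts (default 10,
#'   typical for cultured-neuron MEA recordings).
#' @param units List of [unit_spec] objects.
#' @param seed Integer seed; a fixed seed gives identical output
#'   (Mersenne-Twister with inversion normals, fixed here so results do not
#'   depend on the session's RNG settings).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(layout, duration, sampling_rate = 20000,
                         noise_sigma = 10, units = list(), seed = 1) {
  if (duration <= 0 || noise_sigma < 0)
    rlang::abort("need duration > 0 and noise_sigma >= 0",
                 class = "spikegrid_validation_error")
  for (u in units) {
    bad <- setdiff(u$electrodes, layout$electrodes)
    if (length(bad))
      rlang::abort(sprintf("unit electrode(s) not in layout: %s",
                           paste(bad, collapse = ", ")),
                   class = "spikegrid_validation_error")
  }
  structure(list(layout = layout, duration = duration,
                 sampling_rate = sampling_rate, noise_sigma = noise_sigma,
                 units = units, seed = as.integer(seed)),
            class = "synth_config")
}

draw_event_times <- function(firing, duration, margin) {
  lo <- margin
  hi <- duration - margin
  switch(firing$type,
    poisson = {
      t <- cumsum(stats::rexp(ceiling(firing$rate * duration * 2) + 20,
                              rate = firing$rate)) + lo
      t[t < hi]
    },
    fixed_n = {
      min_isi <- firing$min_isi_ms / 1000
      t <- sort(stats::runif(firing$n, lo, hi))
      # enforce the refractory spacing by resampling violators
      for (iter in 1:100) {
        ok <- c(TRUE, diff(t) >= min_isi)
        if (all(ok)) break
        t[!ok] <- stats::runif(sum(!ok), lo, hi)
        t <- sort(t)
      }
      t
    },
    burst = {
      onsets <- draw_event_times(list(type = "poisson", rate = firing$rate),
                                 duration, margin)
      t <- rep(onsets, each = firing$size) +
        rep((seq_len(firing$size) - 1) * firing$interval_ms / 1000,
            times = length(onsets))
      sort(t[t < hi])
    },
    rlang::abort(sprintf("unknown firing type '%s'", firing$type),
                 class = "spikegrid_parameter_error"))
}

rnorm_trunc0 <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), mean, sd)
  x
}

#' Generate a synthetic MEA recording with ground truth
#'
#' Produces Gaussian background noise plus linearly summed biphasic spike
#' templates at the times dictated by each unit's firing model, together with
#' a ground-truth [spike_table] listing every emitted event (electrode, trough
#' time, trough amplitude, unit id).
#'
#' @param cfg A [synth_config].
#' @return A list with elements `recording` ([analog_recording]) and `truth`
#'   (a [spike_table] with `unit` set to the 1-based unit index).
#' @export
generate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  fs <- cfg$sampling_rate
  n <- round(cfg$duration * fs)
  chans <- cfg$layout$electrodes
  margin <- 0.03  # keep templates and 20 ms extraction windows in-record
  data <- matrix(if (cfg$noise_sigma > 0)
                   stats::rnorm(length(chans) * n, 0, cfg$noise_sigma)
                 else 0,
                 nrow = length(chans), ncol = n,
                 dimnames = list(chans, NULL))

  event_times <- vector("list", length(cfg$units))
  for (i in seq_along(cfg$units)) {
    u <- cfg$units[[i]]
    event_times[[i]] <- if (u$kind == "coupled") {
      pt <- event_times[[u$parent]]
      if (is.null(pt))
        rlang::abort("coupled unit listed before its parent",
                     class = "spikegrid_validation_error")
      pt <- pt[stats::runif(length(pt)) < u$follow_prob]
      sort(pt + rnorm_trunc0(length(pt), u$delay_ms, u$delay_sd_ms) / 1000)
    } else {
      if (!is.null(u$firing$times)) u$firing$times
      else draw_event_times(u$firing, cfg$duration, margin)
    }
  }

  rows <- list()
  for (i in seq_along(cfg$units)) {
    u <- cfg$units[[i]]
    times <- event_times[[i]]
    if (!length(times)) next
    base <- biphasic_template(fs, -1, u$trough_width_ms,
                              u$after_peak_fraction)
    center <- attr(base, "center")
    len <- length(base)
    for (e in seq_along(u$electrodes)) {
      ch <- match(u$electrodes[e], chans)
      tpl <- as.numeric(base) * abs(u$amplitudes_uv[e])
      t_e <- times + u$latencies_ms[e] / 1000 +
        if (u$jitter_ms > 0) stats::rnorm(length(times), 0, u$jitter_ms / 1000)
        else 0
      idx <- round(t_e * fs) + 1L
      keep <- idx - center + 1L >= 1L & idx + (len - center) <= n
      for (k in idx[keep]) {
        span <- (k - center + 1L):(k + len - center)
        data[ch, span] <- data[ch, span] + tpl
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        electrode = u$electrodes[e], time = (idx[keep] - 1) / fs,
        amplitude = u$amplitudes_uv[e], unit = i)
    }
  }
  truth <- if (length(rows)) {
    all <- dplyr::bind_rows(rows)
    spike_table(all$electrode, all$time, all$amplitude, all$unit)
  } else spike_table()
  list(recording = analog_recording(data, chans, fs), truth = truth)
}

#' Built-in synthetic presets
#'
#' Named scenarios used throughout the package's tests and examples:
#' \describe{
#'   \item{`detection-benchmark`}{One channel, 10 uV noise, 100 spikes of
#'     -80 uV trough (8 sigma) over 20 s: ground truth for detector recall
#'     and precision.}
#'   \item{`two-template-sorting`}{One channel, 5 uV noise, two units with
#'     -40 and -120 uV troughs, 200 events each over 60 s: the classic
#'     two-cluster sorting scenario.}
#'   \item{`propagation-demo`}{A 4 x 3 12-electrode grid: one unit whose
#'     action potential propagates along a 6-electrode axonal path (latencies
#'     0-0.75 ms, 0.02 ms jitter, two electrodes with sub-detection-threshold
#'     amplitudes) plus a synaptically coupled follower firing 3 +/- 0.8 ms
#'     after the parent, over 60 s at 2 Hz.}
#' }
#'
#' @param name Preset name.
#' @param seed Integer seed.
#' @param duration Override the preset's duration, seconds.
#' @return A [synth_config].
#' @export
synth_preset <- function(name = c("detection-benchmark",
                                  "two-template-sorting",
                                  "propagation-demo"),
                         seed = 1, duration = NULL) {
  name <- match.arg(name)
  one_ch <- mea_layout("A1", columns = 1, rows = 1, coords = cbind(0, 0))
  cfg <- switch(name,
    "detection-benchmark" = synth_config(
      one_ch, duration = duration %||% 20, noise_sigma = 10,
      units = list(unit_spec("simple", "A1", amplitudes_uv = -80,
                             firing = list(type = "fixed_n", n = 100,
                                           min_isi_ms = 20))),
      seed = seed),
    "two-template-sorting" = synth_config(
      one_ch, duration = duration %||% 60, noise_sigma = 5,
      units = list(
        unit_spec("simple", "A1", amplitudes_uv = -40,
                  firing = list(type = "fixed_n", n = 200, min_isi_ms = 20)),
        unit_spec("simple", "A1", amplitudes_uv = -120,
                  firing = list(type = "fixed_n", n = 200, min_isi_ms = 20))),
      seed = seed),
    "propagation-demo" = {
      cols <- c("A", "B", "C", "D")
      labs <- as.vector(outer(cols, 1:3, paste0))  # A1 B1 C1 D1 A2 ...
      lay <- mea_layout(labs, columns = 4, rows = 3,
                        coords = cbind(rep(0:3, times = 3),
                                       rep(0:2, each = 4)))
      axon <- c("A1", "B1", "C1", "D1", "A2", "B2")
      synth_config(
        lay, duration = duration %||% 60, noise_sigma = 10,
        units = list(
          unit_spec("propagating", axon,
                    latencies_ms = c(0, 0.15, 0.3, 0.45, 0.6, 0.75),
                    amplitudes_uv = c(-80, -75, -70, -65, -40, -35),
                    firing = list(type = "poisson", rate = 2),
                    jitter_ms = 0.02),
          unit_spec("coupled", "C2", amplitudes_uv = -80, parent = 1,
                    delay_ms = 3, delay_sd_ms = 0.8, follow_prob = 0.9)),
        seed = seed)
    })
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
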