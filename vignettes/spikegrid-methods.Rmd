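---
title: "Methods: signal conditioning, spike handling and propagation mapping in spikegrid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal conditioning, spike handling and propagation mapping in spikegrid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikegrid)
```

`spikegrid` processes multi-electrode array (MEA) extracellular recordings:
multi-channel voltage matrices in microvolts at sampling rates around
20 kHz, together with tables of spike timestamps. This vignette explains the
models and procedures behind each stage, the parameters that matter and why
their defaults are what they are, what the synthetic data generator does and
does not emulate, and the numerical choices made where the design was
genuinely open.

## Data model and formats

An `analog_recording` is a channels × samples matrix of voltages (µV) plus a
sampling rate and per-channel electrode labels; a `mea_layout` is a
bijection between those labels and 0-based `(column, row)` grid positions,
origin top-left. Spike events live in plain tibbles (`spike_table`) with
columns `electrode`, `time` (s), `amplitude` (signed peak, µV), `unit`
(integer cluster id, −1 = unsorted) and `redundant`; tables are always
sorted by time with electrode label as a stable tie-break.

On disk, analog data is HDF5 (schema version 1): float32 dataset
`/analog/data` (channels × samples), string dataset `/analog/channels`, and
root attributes `sampling_rate_hz` and `start_time_s`. Float32 halves file
size at a resolution (~0.01 µV on ±100 µV signals) far below electrode
noise. Spike tables are CSV with header `electrode,time,amplitude,unit`
(comma separator, `.` decimal, seconds); a missing `unit` column reads as
−1 everywhere, and the `redundant` column is written only when some flag is
set. Both formats roundtrip exactly up to float32 quantization, which the
test suite asserts on randomized inputs.

The default layout is the common 120-electrode array: a 12 × 12 grid with a
3-2-1 staircase of six sites cut from each corner (144 − 24 = 120), columns
lettered A–M skipping "I" (easily confused with the digit 1), rows numbered
1–12. Which 24 sites a given vendor omits is not standardized; the staircase
is this package's convention, and any other geometry can be built with
`mea_layout()`.

## Band-pass filtering

Extracellular spikes occupy roughly 0.2–4 kHz; slower components (field
potentials, electrode drift) and high-frequency amplifier noise are removed
with a 2nd-order Butterworth band-pass (`filter_spec()`, defaults 200 and
4000 Hz). Two choices are configurable because conventions differ across
labs:

* **Phase.** By default the filter runs forward and backward
  (zero-phase), so spike troughs are not systematically delayed — important
  because detected times feed latency estimates downstream, where a
  systematic per-channel shift would masquerade as propagation delay. A
  causal single pass is available (`zero_phase = FALSE`) for streaming-like
  use; it delays peaks by a fraction of a millisecond.
* **Edges.** Each trace is odd-reflect-padded with one settling length
  (≥ 1000 samples, 50 ms at 20 kHz, several time constants of the 200 Hz
  corner) before filtering, so onset transients never reach the data.

## Robust noise estimation

Detection thresholds are set per channel as a multiple of the noise standard
deviation. On a spiking channel the sample s.d. is badly inflated by the
very events one wants to detect, so `estimate_noise()` uses the
median-based robust scale estimator standard in extracellular work:

σ̂ = median(|x − median(x)|) / 0.6745,

where 0.6745 is the 75th percentile of the standard normal, making σ̂
unbiased for Gaussian noise. With 200 spike waveforms of −120 µV trough
injected into 10 s of 10 µV noise (~3 % of samples touched), σ̂ moves by a
few percent while the plain s.d. is off by ~45 % — the difference between a
stable threshold and one that silently drifts with firing rate.

## Spike detection and waveforms

`detect_spikes()` marks events where the signal crosses
`threshold_multiplier × σ̂` (default 6). Two conventions are deliberate:

* **Event time = local extremum**, not the crossing sample: the extremum
  within one dead time (default 1 ms) after the first crossing. Crossing
  times depend on amplitude; extrema align waveforms stably for averaging.
  The reported amplitude is exactly the signal value at the reported time.
* **Polarity.** The default `"negative"` matches the predominantly negative
  somatic eAP. `"both"` also triggers on positive deflections — including
  the re-polarization hump of large spikes, a classic systematic
  false-positive mode; it is kept as an explicit option so that failure
  mode can be reproduced and inspected rather than met by surprise.

At 6 σ the per-sample tail probability under Gaussian noise is ~10⁻⁹, so a
20 s, 20 kHz noise-only channel should essentially never trigger; the suite
checks 20 seeds and requires at least 19 silent.

`extract_waveforms()` cuts `waveform_window` = 3 ms (61 samples at 20 kHz)
around each event, split symmetrically 1.5 ms before and after the trough
(the split is a convention; nothing downstream depends on it). Events whose
window would cross a record edge are dropped and counted.

## Sorting: PCA + OPTICS

Waveforms are projected onto their first `n_components` = 3 principal
components — enough to separate amplitude- and shape-distinct units while
keeping the density estimate well conditioned — and clustered with OPTICS.
No OPTICS implementation ships with the installed R stack, so the package
carries its own (`optics()`, O(n²) distances, exact priority-queue
ordering; at spike-sorting scale of hundreds to a few thousand events per
electrode this costs well under a second). Its ordering and reachability
were verified to match a reference implementation value-for-value on shared
inputs during development.

Clusters are read off the reachability profile with the ξ-steepness method
(`optics_xi_clusters()`, ξ = 0.05): a cluster is a valley bounded by a
ξ-significant steep-down and steep-up area, with predecessor correction and
a minimum size of `max(5, 5 % of events)`. One extraction detail matters
and is this package's explicit choice: OPTICS visits a cluster's sparse
shell *before* its dense core whenever the scan starts outside, and the
leaf-cluster rule then reports shell and core as separate units. `spikegrid`
therefore labels by **maximal** clusters: the widest clusters of the
hierarchy, discarding a (near-)full-span root only when at least two
disjoint sub-clusters cover ≥ 70 % of the ordering — i.e. when the data are
genuinely multimodal. A single density mode thus stays one unit, while two
units never merge. Leaf labelling remains available
(`extraction = "leaf"`). A sub-sample waveform realignment step was
evaluated and rejected: with sharp troughs the parabolic peak-offset
estimate is noise-dominated and *adds* alignment scatter.

Labels are deterministic for fixed input: no random initialization exists
anywhere in the path (PCA is exact, OPTICS ordering breaks ties by index).

## Redundant co-detections

One neuron's spike is often picked up by several neighbouring electrodes.
`tag_redundant()` flags an event when any event on a *different* electrode
within 0.7 ms dominates it in |amplitude| (label order breaks exact ties),
so the largest co-detection survives as primary. The rule is a pure
pairwise predicate: the outcome is independent of row order, and the suite
checks it against a brute-force all-pairs oracle on random tables.

## Display transforms

**Min/max decimation.** Drawing an n-sample trace into `n_p` pixels by
taking every n/n_p-th sample loses most spikes. `minmax_downsample()`
instead partitions samples into `n_p` near-equal bins (the first
`n mod n_p` bins get one extra sample) and emits each bin's minimum and
maximum *in their order of temporal occurrence* — fixed min-then-max order
would draw phantom zig-zags where the true signal rises. Global extrema are
preserved exactly for every `n_p`, output length is ≤ 2 n_p, and
`n_p ≥ n` returns the raw samples unchanged.

**Raster arithmetic and ordering.** `pixel_duration()` reports
span/pixels in ms/px at 2 significant figures (3 minutes on 1400 px ≈
130 ms/px — wide enough to merge 2–3 spikes of a 20 Hz burst into one
mark, which is why a zoomable raster matters). `order_channels()` orders
channels by descending spike count, by first-spike time after a reference
`t0` (silent channels last), or by an explicit order; all ties break
lexicographically so the view is reproducible.

**Flashing-spike frames.** `spikes_to_frames()` bins the half-open interval
[t_start, t_end) into frames of `playback_factor / frame_rate` seconds of
recording time (1/1600 × real time at 25 fps → 25 µs per frame) and
increments the electrode's grid cell in the frame containing each spike.
Onset counts always sum to the number of spikes in the window; an optional
exponential decay (`decay_frames`) only smooths the *displayed* intensity
and is kept separate from the conserved onsets, since the true flash
duration is a display parameter, not a property of the data.

## Propagation analysis

The key observation: when one neuron's axon crosses several electrodes, a
single action potential appears as near-coincident (≤ 0.7 ms), highly
stereotyped spikes on all of them. Aligning and averaging windows on such a
reference isolates everything time-locked to that one neuron.

* `find_coincident_pairs()` counts one-to-one nearest-neighbour matches
  (two-pointer greedy on sorted times, each spike used once) within the
  coincidence window; pairs with ≥ `min_repeats` = 30 matches count as
  stereotyped. Thirty repeats bounds the averaging noise reduction below
  σ/√30 ≈ 0.18 σ while staying reachable in a minute of recording at
  ordinary firing rates. Both orderings of a pair are reported with equal
  counts; the first-listed channel donates the reference timestamps.
* `extract_aligned()` cuts `extraction_window` = 20 ms (401 samples),
  centered, from **every** channel at each reference time. If any window
  would cross a record edge the event is dropped from *all* channels, so
  every ensemble has the same N and averages are directly comparable.
* `average_ensembles()` computes the per-sample mean trace, the latency of
  its extremum relative to window center, and the jitter: the s.d. of
  per-event extremum latencies, searched within ±1 ms of the mean-trace
  peak and with the mean trace's polarity. The ±1 ms restriction keeps the
  statistic defined at low SNR, at the cost of truncating genuinely large
  jitter near ~0.6 ms — acceptable, since every classification boundary it
  feeds sits well below that ceiling.
* `classify_channels()` applies, in order: **unlocked** when the mean-trace
  peak is below `locked_peak_criterion × σ/√N` (default 4 — the expected
  maximum of ~400 Gaussian residual samples is ≈ 3.5 σ/√N, so 4 keeps the
  false-lock rate on a pure-noise channel near 2–3 %); else **propagation**
  when |latency| ≤ 1 ms and jitter ≤ 0.3 ms; else **coupled** when
  |latency| ∈ [1, 10] ms or jitter > 0.3 ms. The delay range is the
  mono-synaptic regime; the 0.3 ms jitter bound operationalizes the
  qualitative contrast between axonal conduction (tens of µs of jitter) and
  synaptic transmission (hundreds). A locked channel matching neither
  pattern — e.g. |latency| > 10 ms with tiny jitter — stays unlocked rather
  than being forced into a class. `above_threshold` records whether the
  *averaged* peak reaches the detection threshold (per-event amplitudes
  would be the alternative; the averaged peak is used because it is what
  the analysis actually displays and what sub-threshold recovery is about).
* `latency_map()` writes propagation-classified latencies onto the layout
  grid, so conduction order is read directly off the array geometry.

Averaging N windows reduces uncorrelated noise by √N: 400 events of a
0.5 σ template (5 µV trough in 10 µV noise) leave ~0.5 µV of residual
noise, and the recovered mean correlates > 0.9 with the true template over
its support — the mechanism by which sub-threshold events on silent
electrodes become visible.

## The synthetic generator

`generate_recording()` builds: i.i.d. Gaussian background noise per channel
(default σ = 10 µV, typical for cultured-neuron MEAs) plus linearly summed
biphasic templates. A template (`biphasic_template()`) is two
disjoint-support raised-cosine lobes — a sharp trough (default FWHM 0.4 ms)
and a broader positive after-peak (default 0.3 × |trough|) sized so their
areas cancel — total support ≤ 4 ms, the upper end of action-potential
durations. Disjoint supports make the trough and after-peak amplitudes
exact by construction. Unit kinds: `simple` (one electrode), `propagating`
(fixed non-decreasing per-electrode latencies, per-event Gaussian latency
jitter) and `coupled` (fires after a parent with normal, zero-truncated
delay and a follow probability). Firing models: Poisson, exact-count
uniform with refractory spacing, and bursts. Everything derives from one
integer seed with a pinned RNG (Mersenne-Twister, inversion normals), so
output is reproducible across sessions.

The presets are the regimes used throughout the tests: a 100-event 8 σ
detection benchmark (20 s), the −40/−120 µV two-unit sorting scenario
(200 + 200 events, σ = 5 µV, 60 s), and the propagation demo (4 × 3 grid,
6-electrode axon with latencies 0–0.75 ms and 0.02 ms jitter, amplitudes
−80…−35 µV of which two are sub-threshold, plus a follower at
3 ± 0.8 ms, firing 2 Hz over 60 s).

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: correlated or non-Gaussian noise (line hum,
shared-reference artifacts, 1/f field potentials), waveform variability and
electrode drift over time, bursting adaptation and amplitude rundown,
overlapping-spike decomposition beyond linear summation, and conduction
velocity changes. Results on real recordings depend on those factors;
the synthetic suite validates the machinery, not the biology.

## Problem sizes and numerical choices

The test and acceptance runs use: 20 s single-channel records for detection
(400 k samples), 20 noise seeds of 20 s for the false-positive check,
n = 200 000 for noise-estimator accuracy, 200 random signals × 4 pixel
budgets for decimation, 400 aligned windows for sub-threshold recovery, and
10 seeds of the 60 s, 12-channel propagation demo — sizes chosen so each
statistical claim has comfortable margin while a full run stays in the
minutes range on one CPU.

Degenerate inputs are defined, not accidental: empty spike tables are valid
everywhere (empty frames, empty raster), `n_p ≥ n` passes samples through,
an all-zero signal detects nothing, fewer events than the minimum cluster
size sort to −1 with a warning, and a pair reference with zero coincidences
returns an empty time vector with a warning. Exact ties — equal spike
counts, equal amplitudes, equidistant reachabilities — always break by
label or index order so that every result is reproducible to the byte.

## Known limitations

The OPTICS implementation is quadratic in events per electrode; beyond
~10⁴ events a specialized index would be needed. Latency resolution is one
sample (50 µs at 20 kHz); sub-sample latency interpolation is deliberately
absent (see the realignment note above). Classification thresholds are
biologically motivated defaults, not fitted quantities, and are all exposed
in `propagation_config()`. The CLI covers the common paths; programmatic
use through the package functions is the primary interface.
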