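# spikegrid

Analysis toolkit for multi-electrode array (MEA) extracellular recordings.

Planar MEAs record extracellular action potentials (eAPs, "spikes") from
dozens to hundreds of cultured or in-vivo neurons at once. A typical
120-electrode recording at 20 kHz produces hundreds of megabytes per minute,
and the standard workflow — band-pass filter, threshold detection, waveform
sorting — both discards most of the raw signal and is famously error prone.
`spikegrid` implements the computational layer such recordings need:

- **Interchange formats**: HDF5 analog voltage files and CSV spike-timestamp
  tables, plus electrode-grid `Layout` objects mapping labels like `"F8"` to
  `(column, row)` positions. The built-in `default_layout()` is the common
  120-electrode, 12 × 12 grid with staircase corner cuts.
- **Signal conditioning**: zero-phase 2nd-order Butterworth band-pass
  (0.2–4 kHz defaults) and a robust noise estimate
  σ̂ = median(|x − median(x)|) / 0.6745, which sparse large spikes barely
  perturb — unlike the plain standard deviation they badly inflate.
- **Detection & sorting**: threshold crossing at 6 σ̂ with the event placed
  on the local extremum, 3 ms waveform extraction, PCA projection and OPTICS
  density clustering (implemented in-package, with ξ-steepness cluster
  extraction), and tagging of redundant co-detections of one neuron on
  several electrodes (0.7 ms coincidence window).
- **Display transforms**: extrema-preserving min/max decimation (a spike is
  never lost no matter how few pixels it is drawn into), raster orderings by
  activity / latency / fixed order, ms-per-pixel arithmetic, and
  spatiotemporal frame binning for flashing-spike animations at playback
  factors down to 1/1600 of real time.
- **Propagation analysis**: stereotyped coincident spiking between channels
  (repeated events within 0.7 ms) defines a reference; 20 ms windows from
  every channel are aligned on the reference spike times and averaged,
  reducing uncorrelated noise by √N and recovering time-locked waveforms far
  below the detection threshold. Channels are classified as **propagation**
  (|latency| ≤ 1 ms, jitter ≤ 0.3 ms — one action potential travelling
  along an axon), **coupled** (1–10 ms delay or high jitter — pre-/
  post-synaptic partner spiking) or **unlocked**, and propagation latencies
  are mapped back onto the array geometry.
- **Synthetic recordings**: a seeded generator of Gaussian-noise recordings
  with biphasic spike templates — simple units, propagating axonal paths
  with fixed inter-electrode latencies, and jittered synaptically coupled
  followers — with exact ground truth, so every stage is testable end to
  end.

Everything tabular flows through tibbles, so results chain with the pipe and
plot with `autoplot()`; fitted results have `tidy()` and `glance()` methods.

## Worked example: finding an axon and its synaptic partner

The `propagation-demo` preset simulates a 4 × 3 grid in which one neuron's
action potential propagates along six electrodes (latencies 0–0.75 ms, two
of the six with amplitudes below the 6 σ̂ detection threshold) and a coupled
follower fires ~3 ms later with 0.8 ms jitter:

```r
library(spikegrid)

out    <- generate_recording(synth_preset("propagation-demo", seed = 7))
spikes <- detect_recording(out$recording)
result <- propagation_analysis(out$recording, spikes, c("A1", "B1"))
tidy(result)
#>    electrode peak_latency_ms jitter_ms peak_uv above_threshold classification
#> 1         A1            0.00    0.0000  -88.15            TRUE    propagation
#> 2         B1            0.15    0.0779  -73.23            TRUE    propagation
#> 3         C1            0.30    0.0755  -66.76            TRUE    propagation
#> 4         D1            0.45    0.0825  -61.66            TRUE    propagation
#> 5         A2            0.60    0.0991  -36.66           FALSE    propagation
#> 6         B2            0.75    0.0927  -33.86           FALSE    propagation
#> 7         C2            2.40    0.5967  -14.89           FALSE        coupled
#> 8         D2           -8.80    0.5787   -2.88           FALSE       unlocked
#> ...
```

Reading the table: the six axonal electrodes are recovered with their
injected latencies (0, 0.15, …, 0.75 ms) and tight jitter, *including* `A2`
and `B2`, whose −40/−35 µV spikes never cross the 60 µV detection threshold
— averaging 115 aligned windows pushed the residual noise down to
10/√115 ≈ 0.9 µV. The follower `C2` is separated by its 2.4 ms mean delay
and ~0.6 ms jitter; all other channels carry no time-locked signal. The
latency map mirrors the array geometry:

```r
latency_map(result, synth_preset("propagation-demo", seed = 7)$layout)
#>      [,1] [,2] [,3] [,4]
#> [1,]  0.0 0.15  0.3 0.45
#> [2,]  0.6 0.75   NA   NA
#> [3,]   NA   NA   NA   NA
```

A shell entry point wraps the same functions
(`Rscript inst/cli/spikegrid.R --help`; subcommands `synth`, `filter`,
`detect`, `sort`, `downsample`, `raster`, `frames`, `propagation`).

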