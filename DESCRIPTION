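Package: spikegrid
Title: Multi-Electrode Array Spike Detection, Sorting and Propagation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with multi-electrode array (MEA) extracellular
    recordings: HDF5 analog and CSV spike-timestamp interchange formats,
    electrode-grid layouts, Butterworth band-pass conditioning, robust
    median-based noise estimation, threshold spike detection, waveform
    extraction, PCA plus OPTICS spike sorting, multi-electrode redundancy
    tagging, extrema-preserving min/max downsampling for display, raster
    orderings and spatiotemporal frame binning, and spike-triggered signal
    averaging that maps axonal action-potential propagation latencies and
    recovers sub-threshold time-locked events. Includes a seeded synthetic
    MEA recording generator with ground truth and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rhdf5,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
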