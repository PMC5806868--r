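fs <- 20000

test_that("min/max downsampling never loses extrema", {
  # a lone spike among zeros survives any pixel budget
  x <- numeric(10000)
  x[5000] <- -100
  ds <- minmax_downsample(x, fs, 100)
  expect_true(-100 %in% ds$value)
  expect_equal(nrow(ds), 200)
  # randomized property over signals and pixel counts
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(50:5000, 1)
    x <- rnorm(n, 0, 10)
    for (n_p in c(1, 7, 64, n - 1, n, n + 10)) {
      ds <- minmax_downsample(x, fs, n_p)
      expect_equal(min(ds$value), min(x))
      expect_equal(max(ds$value), max(x))
      expect_lte(nrow(ds), 2 * n_p)
      # against the brute-force per-bin oracle
      if (n_p < n)
        expect_setequal(round(ds$value, 10), round(minmax_oracle(x, n_p), 10))
    }
  }
})

test_that("downsampling edge behavior: constants, passthrough, errors", {
  x <- rep(5, 500)
  expect_true(all(minmax_downsample(x, fs, 10)$value == 5))
  x2 <- rnorm(100)
  expect_equal(minmax_downsample(x2, fs, 100)$value, x2)  # passthrough
  expect_equal(minmax_downsample(x2, fs, 500)$value, x2)
  expect_error(minmax_downsample(x2, fs, 0),
               class = "spikegrid_parameter_error")
  # min/max emitted in temporal order within each bin
  x3 <- c(0, 10, -10, 0)  # max before min in the single bin
  ds <- minmax_downsample(x3, fs, 1)
  expect_equal(ds$value, c(10, -10))
})

test_that("pixel duration arithmetic matches the quoted display regime", {
  expect_equal(pixel_duration(180, 1400), 130)  # 3 min @ 1400 px
  expect_equal(pixel_duration(1, 1000), 1.0)
  expect_equal(pixel_duration(10, 1), 10000)
  expect_error(pixel_duration(0, 100), class = "spikegrid_parameter_error")
})

test_that("channel ordering schemes sort and tie-break as documented", {
  tb <- spike_table(c(rep("A1", 5), rep("B2", 10), "C3"),
                    sort(runif(16, 0, 1)), rep(-50, 16))
  expect_equal(order_channels(tb, "activity")$channels, c("B2", "A1", "C3"))
  # all-equal counts fall back to label order
  tb2 <- spike_table(c("B2", "A1", "C3"), c(0.3, 0.2, 0.1), rep(-50, 3))
  expect_equal(order_channels(tb2, "activity")$channels, c("A1", "B2", "C3"))
  # latency from t0: first spike at/after t0 decides; silent channels last
  tb3 <- spike_table(c("A1", "B2", "C3"), c(0.002, 0.001, -0 + 0.0005),
                     rep(-50, 3))
  rv <- order_channels(tb3, "latency", t0 = 0.0008)
  expect_equal(rv$channels, c("B2", "A1", "C3"))
  # fixed ordering must be a permutation
  rv2 <- order_channels(tb3, "fixed", fixed_order = c("C3", "A1", "B2"))
  expect_equal(rv2$channels, c("C3", "A1", "B2"))
  expect_error(order_channels(tb3, "fixed", fixed_order = c("C3", "A1")),
               class = "spikegrid_parameter_error")
  expect_error(order_channels(tb3, "latency"),
               class = "spikegrid_parameter_error")
  expect_error(order_channels(tb3, "sideways"),
               class = "spikegrid_parameter_error")
})

test_that("every ordering scheme returns each channel exactly once", {
  set.seed(12)
  chans <- c("A1", "B1", "C1", "D1", "E1")
  tb <- spike_table(sample(chans, 200, TRUE), sort(runif(200, 0, 10)),
                    rep(-40, 200))
  for (rv in list(order_channels(tb, "activity"),
                  order_channels(tb, "latency", t0 = 5),
                  order_channels(tb, "fixed", fixed_order = rev(chans)))) {
    expect_setequal(rv$channels, chans)
    expect_equal(anyDuplicated(rv$channels), 0L)
    expect_equal(nrow(rv$spikes), 200)
  }
})

test_that("spike-to-frame binning conserves onsets on the half-open window", {
  lay <- default_layout()
  tb <- spike_table(rep("F8", 10), seq(1, 1.9, by = 0.1), rep(-50, 10))
  fseq <- spikes_to_frames(tb, lay, 1, 2, frame_rate = 25,
                           playback_factor = 1)
  co <- coordinates_for_electrode(lay, "F8")
  total <- sum(vapply(fseq$onsets, function(m)
    m[co["row"] + 1, co["column"] + 1], numeric(1)))
  expect_equal(total, 10)
  # spike exactly at t_end excluded
  tb2 <- spike_table(c("F8", "F8"), c(1.0, 2.0), c(-50, -50))
  f2 <- spikes_to_frames(tb2, lay, 1, 2)
  expect_equal(sum(unlist(f2$onsets)), 1)
  # frame span arithmetic: 25 fps at 1/1600 playback -> 25 us per frame
  f3 <- spikes_to_frames(tb, lay, 1, 1.001, frame_rate = 25,
                         playback_factor = 1 / 1600)
  expect_equal(f3$frame_span, 25e-6)
  # empty table: all frames zero
  f4 <- spikes_to_frames(spike_table(), lay, 0, 1)
  expect_true(all(unlist(f4$frames) == 0))
})

test_that("frame conservation holds for random tables; errors are raised", {
  lay <- default_layout()
  set.seed(31)
  for (i in 1:3) {
    tb <- spike_table(sample(lay$electrodes, 100, TRUE),
                      runif(100, 0, 2), rep(-40, 100))
    fseq <- spikes_to_frames(tb, lay, 0, 2, frame_rate = 30,
                             playback_factor = 0.5)
    inside <- sum(tb$time >= 0 & tb$time < 2)
    expect_equal(sum(unlist(fseq$onsets)), inside)
  }
  tb <- spike_table("ZZ", 0.5, -40)
  expect_error(spikes_to_frames(tb, lay, 0, 1),
               class = "spikegrid_lookup_error")
  expect_error(spikes_to_frames(spike_table(), lay, 1, 1),
               class = "spikegrid_parameter_error")
  expect_error(spikes_to_frames(spike_table(), lay, 0, 1,
                                playback_factor = 1 / 3200),
               class = "spikegrid_parameter_error")
})
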