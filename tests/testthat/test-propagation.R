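fs <- 20000

test_that("coincident pair finding matches the brute-force matcher", {
  set.seed(41)
  ta <- sort(runif(50, 0.1, 59.9))
  tb <- ta + 3e-4  # +0.3 ms
  tc <- ta + 1.5e-3  # +1.5 ms: outside the window
  tab <- spike_table(c(rep("A1", 50), rep("B1", 50), rep("C1", 50)),
                     c(ta, tb, tc), rep(-60, 150))
  pairs <- find_coincident_pairs(tab, propagation_config())
  ab <- pairs[pairs$electrode_a == "A1" & pairs$electrode_b == "B1", ]
  expect_equal(ab$count, 50)
  expect_equal(ab$count,
               coincidence_oracle(ta, tb, 0.7e-3))
  expect_false(any(pairs$electrode_a == "A1" & pairs$electrode_b == "C1"))
  # symmetry: both orderings present with equal counts
  ba <- pairs[pairs$electrode_a == "B1" & pairs$electrode_b == "A1", ]
  expect_equal(ba$count, ab$count)
  # single channel: nothing to pair
  expect_equal(nrow(find_coincident_pairs(
    spike_table(rep("A1", 40), sort(runif(40)), rep(-50, 40)))), 0)
})

test_that("pair reference times are the matched events of the first channel", {
  set.seed(42)
  ta <- sort(runif(60, 0.1, 59.9))
  keep <- sort(sample(60, 50))
  tb <- ta[keep] + 2e-4
  tab <- spike_table(c(rep("A1", 60), rep("B1", 50)), c(ta, tb),
                     rep(-60, 110))
  rt <- reference_times(tab, c("A1", "B1"))
  expect_equal(rt, ta[keep])
  # sorted-unit reference filters on the unit label
  tab2 <- spike_table(rep("A1", 10), sort(runif(10)), rep(-60, 10),
                      unit = rep(c(1L, 2L), 5))
  rt2 <- reference_times(tab2, "A1", unit = 2L)
  expect_equal(rt2, sort(tab2$time[tab2$unit == 2L]))
  expect_error(reference_times(tab2, "Q9"),
               class = "spikegrid_lookup_error")
  # a pair with no matches warns and returns nothing
  tab3 <- spike_table(c("A1", "B1"), c(0.1, 0.5), c(-60, -60))
  expect_warning(rt3 <- reference_times(tab3, c("A1", "B1")),
                 "no coincidences")
  expect_length(rt3, 0)
})

test_that("aligned extraction windows are exact and equal-N across channels", {
  lay <- mea_layout(c("A1", "B1"), 2, 1, cbind(0:1, c(0, 0)))
  cfg <- synth_config(lay, duration = 10, noise_sigma = 0,
                      units = list(unit_spec(
                        "propagating", c("A1", "B1"),
                        latencies_ms = c(0, 0.3),
                        amplitudes_uv = c(-80, -50),
                        firing = list(type = "fixed_n", n = 20,
                                      min_isi_ms = 50))),
                      seed = 2)
  out <- generate_recording(cfg)
  ref <- out$truth$time[out$truth$electrode == "A1"]
  res <- extract_aligned(out$recording, ref)
  expect_equal(ncol(res$ensembles[["A1"]]$windows), round(0.020 * fs) + 1)
  expect_equal(res$n_events, 20)
  # every window equals the local signal exactly (noise-free)
  w1 <- res$ensembles[["A1"]]$windows
  expect_true(all(apply(w1, 1, min) == -80))
  # a reference time too close to the record edge drops the event everywhere
  res2 <- extract_aligned(out$recording, c(0.005, ref))
  expect_equal(res2$n_events, 20)
  expect_equal(res2$n_dropped, 1L)
  expect_equal(nrow(res2$ensembles[["B1"]]$windows), 20)
  expect_error(extract_aligned(out$recording, 0.001),
               class = "spikegrid_input_error")
})

test_that("averaging identical windows returns the window with zero jitter", {
  lay <- mea_layout("A1", 1, 1, cbind(0, 0))
  cfg <- synth_config(lay, duration = 10, noise_sigma = 0,
                      units = list(unit_spec(
                        "simple", "A1", amplitudes_uv = -80,
                        firing = list(type = "fixed_n", n = 15,
                                      min_isi_ms = 100))),
                      seed = 3)
  out <- generate_recording(cfg)
  res <- average_ensembles(extract_aligned(
    out$recording, out$truth$time))
  en <- res$ensembles[["A1"]]
  expect_equal(en$mean_trace, en$windows[1, ])
  expect_equal(en$jitter, 0)
  expect_equal(en$peak_latency, 0)
})

test_that("averaging 400 windows recovers a 0.5-sigma template", {
  lay <- mea_layout("A1", 1, 1, cbind(0, 0))
  cfg <- synth_config(lay, duration = 110, noise_sigma = 10,
                      units = list(unit_spec(
                        "simple", "A1", amplitudes_uv = -5,  # 0.5 sigma
                        firing = list(type = "fixed_n", n = 400,
                                      min_isi_ms = 25))),
                      seed = 4)
  out <- generate_recording(cfg)
  res <- average_ensembles(extract_aligned(out$recording, out$truth$time))
  mt <- res$ensembles[["A1"]]$mean_trace
  tpl <- as.numeric(biphasic_template(fs, -5))
  center <- res$center
  tcenter <- attr(biphasic_template(fs, -5), "center")
  span <- (center - tcenter + 1L):(center + length(tpl) - tcenter)
  expect_gt(cor(mt[span], tpl), 0.9)
  # residual noise shrinks like sigma / sqrt(N)
  truth_trace <- numeric(length(mt))
  truth_trace[span] <- tpl
  resid <- mt - truth_trace
  expect_lt(abs(sd(resid) - 10 / sqrt(400)) / (10 / sqrt(400)), 0.2)
})

test_that("all-noise ensembles stay below the locked-peak criterion", {
  lay <- mea_layout("A1", 1, 1, cbind(0, 0))
  hits <- vapply(1:20, function(seed) {
    cfg <- synth_config(lay, duration = 30, noise_sigma = 10,
                        units = list(), seed = seed)
    rec <- generate_recording(cfg)$recording
    set.seed(seed + 1000)
    times <- sort(runif(100, 0.05, 29.95))
    res <- average_ensembles(extract_aligned(rec, times))
    peak <- max(abs(res$ensembles[["A1"]]$mean_trace))
    peak < 4 * 10 / sqrt(res$n_events)
  }, logical(1))
  expect_gte(sum(hits), 19)
})

test_that("averaging noise scales as sigma over sqrt(N)", {
  lay <- mea_layout("A1", 1, 1, cbind(0, 0))
  cfg <- synth_config(lay, duration = 120, noise_sigma = 10,
                      units = list(), seed = 5)
  rec <- generate_recording(cfg)$recording
  set.seed(6)
  times <- sort(runif(400, 0.05, 119.95))
  for (n in c(25, 100, 400)) {
    res <- average_ensembles(extract_aligned(rec, times[seq_len(n)]))
    s <- sd(res$ensembles[["A1"]]$mean_trace)
    expect_lt(abs(s - 10 / sqrt(n)) / (10 / sqrt(n)), 0.2)
  }
})

test_that("classification separates propagation, coupled and unlocked", {
  out <- generate_recording(synth_preset("propagation-demo", seed = 51))
  rec <- out$recording
  det <- detect_recording(rec)
  res <- propagation_analysis(rec, det, c("A1", "B1"))
  cls <- tidy(res)
  axon <- c("A1", "B1", "C1", "D1", "A2", "B2")
  expect_true(all(cls$classification[cls$electrode %in% axon] ==
                    "propagation"))
  expect_equal(cls$classification[cls$electrode == "C2"], "coupled")
  # the two weak axonal electrodes are recovered below detection threshold
  expect_false(any(cls$above_threshold[cls$electrode %in% c("A2", "B2")]))
  expect_true(all(cls$above_threshold[cls$electrode %in%
                                        c("A1", "B1", "C1", "D1")]))
  # remaining channels carry no locked signal
  rest <- setdiff(cls$electrode, c(axon, "C2"))
  expect_true(all(cls$classification[cls$electrode %in% rest] == "unlocked"))
})

test_that("latency map mirrors the axonal gradient on the grid", {
  out <- generate_recording(synth_preset("propagation-demo", seed = 52))
  rec <- out$recording
  det <- detect_recording(rec)
  res <- propagation_analysis(rec, det, c("A1", "B1"))
  lay <- synth_preset("propagation-demo", seed = 52)$layout
  lm <- latency_map(res, lay)
  tb <- tibble::as_tibble(lm)
  lat <- tb$latency_ms[match(c("A1", "B1", "C1", "D1", "A2", "B2"),
                             tb$electrode)]
  expect_false(any(is.na(lat)))
  expect_true(all(diff(lat) > 0))  # monotone along the path
  expect_equal(lat, c(0, 0.15, 0.3, 0.45, 0.6, 0.75), tolerance = 0.15)
  expect_true(is.na(tb$latency_ms[tb$electrode == "C2"]))
  # no propagation channels: empty map with a warning
  res_noise <- res
  for (ch in names(res_noise$ensembles))
    res_noise$ensembles[[ch]]$classification <- "unlocked"
  expect_warning(lm2 <- latency_map(res_noise, lay), "empty")
  expect_true(all(is.na(lm2)))
})

test_that("synthetic construction hits the classification rules directly", {
  # fixed latency 0.4 ms, tiny jitter, strong amplitude -> propagation
  lay <- mea_layout(c("A1", "B1"), 2, 1, cbind(0:1, c(0, 0)))
  cfg <- synth_config(lay, duration = 40, noise_sigma = 5,
                      units = list(unit_spec(
                        "propagating", c("A1", "B1"),
                        latencies_ms = c(0, 0.4),
                        amplitudes_uv = c(-80, -60),
                        firing = list(type = "fixed_n", n = 60,
                                      min_isi_ms = 60),
                        jitter_ms = 0.02)),
                      seed = 7)
  out <- generate_recording(cfg)
  res <- propagation_analysis(out$recording,
                              detect_recording(out$recording), "A1")
  expect_equal(tidy(res)$classification, c("propagation", "propagation"))
  # latency 4 ms with 0.8 ms jitter -> coupled
  cfg2 <- synth_config(lay, duration = 40, noise_sigma = 5,
                       units = list(
                         unit_spec("simple", "A1", amplitudes_uv = -80,
                                   firing = list(type = "fixed_n", n = 60,
                                                 min_isi_ms = 60)),
                         unit_spec("coupled", "B1", amplitudes_uv = -80,
                                   parent = 1, delay_ms = 4,
                                   delay_sd_ms = 0.8, follow_prob = 1)),
                       seed = 8)
  out2 <- generate_recording(cfg2)
  res2 <- propagation_analysis(out2$recording,
                               detect_recording(out2$recording), "A1")
  cls2 <- tidy(res2)
  expect_equal(cls2$classification[cls2$electrode == "B1"], "coupled")
})
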