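# Independent brute-force oracles used across the suite.

# match detections to ground truth within tol seconds, one-to-one greedy
match_to_truth <- function(detected, truth, tol = 5e-4) {
  used <- rep(FALSE, length(truth))
  hits <- logical(length(detected))
  for (i in seq_along(detected)) {
    d <- abs(truth - detected[i])
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= tol) {
      hits[i] <- TRUE
      used[j] <- TRUE
    }
  }
  list(recall = sum(used) / length(truth),
       precision = mean(hits))
}

# purity of cluster labels against true unit ids (clustered events only)
label_purity <- function(labels, truth_units) {
  keep <- labels >= 0 & !is.na(truth_units)
  if (!sum(keep)) return(NA_real_)
  tab <- table(labels[keep], truth_units[keep])
  sum(apply(tab, 1, max)) / sum(keep)
}

# O(n^2) all-pairs redundancy oracle: an event is redundant iff some event
# on another electrode within the window dominates it in |amplitude|
# (electrode label breaks exact amplitude ties)
redundant_oracle <- function(tbl, window_ms = 0.7) {
  w <- window_ms / 1000
  n <- nrow(tbl)
  out <- rep(FALSE, n)
  for (k in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j == k || tbl$electrode[j] == tbl$electrode[k]) next
      if (abs(tbl$time[j] - tbl$time[k]) > w) next
      if (abs(tbl$amplitude[j]) > abs(tbl$amplitude[k]) ||
          (abs(tbl$amplitude[j]) == abs(tbl$amplitude[k]) &&
           tbl$electrode[j] < tbl$electrode[k])) {
        out[k] <- TRUE
        break
      }
    }
  }
  out
}

# brute-force per-bin min/max downsample oracle (near-equal partition)
minmax_oracle <- function(signal, n_p) {
  n <- length(signal)
  sizes <- rep(n %/% n_p, n_p)
  if (n %% n_p) sizes[seq_len(n %% n_p)] <- sizes[seq_len(n %% n_p)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  unlist(lapply(seq_len(n_p), function(b) {
    seg <- signal[starts[b]:ends[b]]
    range(seg)
  }))
}

# greedy nearest-in-time one-to-one coincidence count, written as a plain
# double loop independent of the package's two-pointer implementation
coincidence_oracle <- function(ta, tb, w) {
  ta <- sort(ta)
  tb <- sort(tb)
  used <- rep(FALSE, length(tb))
  count <- 0L
  for (i in seq_along(ta)) {
    best <- NA_integer_
    bestd <- w
    for (j in seq_along(tb)) {
      if (used[j]) next
      d <- abs(ta[i] - tb[j])
      if (d <= bestd) {
        best <- j
        bestd <- d
      }
    }
    if (!is.na(best)) {
      used[best] <- TRUE
      count <- count + 1L
    }
  }
  count
}

# a tiny deterministic recording for io tests
toy_recording <- function(seed = 1, channels = 4, samples = 1000,
                          fs = 20000) {
  set.seed(seed)
  analog_recording(matrix(stats::rnorm(channels * samples), channels),
                   paste0("CH", seq_len(channels)), fs)
}
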