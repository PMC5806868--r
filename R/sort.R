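#' Spike sorting configuration
#'
#' @param n_components Number of principal components kept before
#'   clustering (default 3).
#' @param min_cluster_fraction Minimum cluster size as a fraction of the
#'   event count (default 0.05), with an absolute floor of 5 events.
#' @param xi Steepness threshold for OPTICS cluster extraction; see
#'   [optics_xi_clusters()].
#' @return An object of class `sort_config`.
#' @export
sort_config <- function(n_components = 3, min_cluster_fraction = 0.05,
                        xi = 0.05) {
  if (n_components < 1)
    rlang::abort("n_components must be >= 1",
                 class = "spikegrid_parameter_error")
  if (min_cluster_fraction <= 0 || min_cluster_fraction >= 1)
    rlang::abort("min_cluster_fraction must be in (0, 1)",
                 class = "spikegrid_parameter_error")
  structure(list(n_components = as.integer(n_components),
                 min_cluster_fraction = min_cluster_fraction, xi = xi),
            class = "sort_config")
}

#' Sort spike waveforms into putative units
#'
#' Reduces waveforms to `n_components` principal components
#' ([stats::prcomp()]) and clusters the scores with OPTICS plus xi-steepness
#' extraction. Labels are integers starting at 0; density-noise events get
#' -1. The procedure is deterministic for fixed inputs and configuration.
#'
#' @param wfs A [waveform_set] from [extract_waveforms()].
#' @param cfg A [sort_config].
#' @return Integer vector of unit labels, one per event.
#' @export
sort_spikes <- function(wfs, cfg = sort_config()) {
  n <- nrow(wfs$events)
  min_size <- max(5L, ceiling(cfg$min_cluster_fraction * n))
  if (n < max(2L, min_size)) {
    rlang::warn(sprintf(
      "%d events is below the minimum cluster size (%d); all labelled -1",
      n, min_size))
    return(rep(-1L, n))
  }
  k <- min(cfg$n_components, ncol(wfs$events), n)
  scores <- stats::prcomp(wfs$events, center = TRUE,
                          scale. = FALSE)$x[, seq_len(k), drop = FALSE]
  opt <- optics(scores, minPts = min_size)
  optics_xi_clusters(opt, xi = cfg$xi, minPts = min_size,
                     min_cluster_size = min_size)
}

#' Project waveforms to principal components
#'
#' The projection stage of [sort_spikes()], exposed for inspection and
#' plotting.
#'
#' @inheritParams sort_spikes
#' @return A tibble with one row per event and columns `PC1..PCk`.
#' @export
waveform_pcs <- function(wfs, cfg = sort_config()) {
  k <- min(cfg$n_components, ncol(wfs$events), nrow(wfs$events))
  scores <- stats::prcomp(wfs$events, center = TRUE,
                          scale. = FALSE)$x[, seq_len(k), drop = FALSE]
  tibble::as_tibble(as.data.frame(scores))
}

#' Tag redundant multi-electrode co-detections
#'
#' An action potential from one neuron is often picked up by several nearby
#' electrodes. Spikes on *different* electrodes that fall within
#' `window` ms of each other are grouped, and every member except the one
#' with the largest absolute amplitude is flagged `redundant`. Events on a
#' single electrode are never flagged. The outcome does not depend on the
#' input row order.
#'
#' @param table A [spike_table] (sorted by time).
#' @param window Coincidence window, ms (default 0.7).
#' @return The table with its `redundant` column filled in.
#' @export
tag_redundant <- function(table, window = 0.7) {
  tbl <- dplyr::arrange(table, .data$time, .data$electrode)
  n <- nrow(tbl)
  tbl$redundant <- rep(FALSE, n)
  if (n < 2) return(tbl)
  w <- window / 1000
  # an event is redundant when a coincident spike on another electrode
  # dominates it in |amplitude| (label order breaks exact ties)
  dominates <- function(j, k) {
    abs(tbl$amplitude[j]) > abs(tbl$amplitude[k]) ||
      (abs(tbl$amplitude[j]) == abs(tbl$amplitude[k]) &&
         tbl$electrode[j] < tbl$electrode[k])
  }
  lo <- 1L
  for (k in seq_len(n)) {
    while (tbl$time[k] - tbl$time[lo] > w) lo <- lo + 1L
    hi <- k
    while (hi < n && tbl$time[hi + 1L] - tbl$time[k] <= w) hi <- hi + 1L
    for (j in lo:hi) {
      if (j != k && tbl$electrode[j] != tbl$electrode[k] && dominates(j, k)) {
        tbl$redundant[k] <- TRUE
        break
      }
    }
  }
  tbl
}
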