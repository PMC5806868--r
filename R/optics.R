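# OPTICS density ordering (Ankerst et al. 1999) with xi-steepness cluster
# extraction. Written against the original algorithm; O(n^2) distances, which
# is fine at spike-sorting scale (hundreds to a few thousand events).

#' OPTICS density-based cluster ordering
#'
#' Computes the OPTICS ordering, reachability distances and predecessors for
#' a point set. `minPts` sets the density scale: a point's core distance is
#' the distance to its `minPts`-th nearest neighbour (the point itself
#' counting first).
#'
#' @param x Numeric matrix, points in rows.
#' @param minPts Minimum number of points for a dense neighbourhood.
#' @return A list with `order` (visit order, point indices), `reachability`
#'   and `core_dist` (per point, `Inf` where undefined) and `predecessor`.
#' @export
optics <- function(x, minPts) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (minPts > n) minPts <- n
  d <- as.matrix(stats::dist(x))
  core <- apply(d, 1, function(r) sort(r, partial = minPts)[minPts])
  reach <- rep(Inf, n)
  pred <- rep(NA_integer_, n)
  processed <- rep(FALSE, n)
  ord <- integer(n)
  k <- 0L
  seed_reach <- rep(Inf, n)   # reachability of points waiting in the queue
  for (start in seq_len(n)) {
    if (processed[start]) next
    p <- start
    repeat {
      processed[p] <- TRUE
      k <- k + 1L
      ord[k] <- p
      seed_reach[p] <- Inf
      # update queue from p's neighbourhood
      newreach <- pmax(core[p], d[p, ])
      better <- !processed & newreach < seed_reach
      if (any(better)) {
        seed_reach[better] <- newreach[better]
        reach[better] <- newreach[better]
        pred[better] <- p
      }
      if (all(seed_reach == Inf)) break
      p <- which.min(seed_reach)  # ties: smallest index
    }
  }
  list(order = ord, reachability = reach, core_dist = core,
       predecessor = pred)
}

# extend a steep region: tolerate up to minPts consecutive non-steep points
# that still move in the region's direction; a counter-direction point ends it
extend_region <- function(steep, counter, start, minPts) {
  n <- length(steep)
  index <- start
  end <- start
  slack <- 0L
  while (index <= n) {
    if (steep[index]) {
      slack <- 0L
      end <- index
    } else if (!counter[index]) {
      slack <- slack + 1L
      if (slack > minPts) break
    } else {
      return(end)
    }
    index <- index + 1L
  }
  end
}

filter_sdas <- function(sdas, mib, xic, rplot) {
  if (is.infinite(mib)) return(list())
  keep <- Filter(function(s) mib <= rplot[s$start] * xic, sdas)
  lapply(keep, function(s) { s$mib <- max(s$mib, mib); s })
}

correct_predecessor <- function(rplot, pplot, order, c_start, c_end) {
  while (c_start < c_end) {
    if (rplot[c_start] > rplot[c_end]) return(c(c_start, c_end))
    p <- pplot[c_end]
    if (!is.na(p) && p %in% order[c_start:(c_end - 1L)])
      return(c(c_start, c_end))
    c_end <- c_end - 1L
  }
  NULL
}

#' Extract clusters from an OPTICS ordering (xi method)
#'
#' Finds clusters as valleys in the reachability plot bounded by
#' xi-significant steep-down and steep-up areas, with predecessor correction,
#' and labels points by the leaf clusters of the resulting hierarchy. Points
#' in no cluster get label -1 (density noise).
#'
#' @param opt Result of [optics()].
#' @param xi Steepness threshold in (0, 1); larger values demand more
#'   pronounced valleys.
#' @param minPts The `minPts` used for the ordering.
#' @param min_cluster_size Minimum number of points in a reported cluster.
#' @param extraction `"maximal"` (default) labels points by the widest
#'   clusters of the hierarchy, excluding a cluster that spans the whole
#'   ordering whenever finer structure exists beneath it; `"leaf"` labels by
#'   the narrowest (most specific) clusters. Maximal extraction keeps each
#'   density mode in one piece even when its sparser shell is ordered ahead
#'   of its core, which the leaf rule would split off.
#' @return Integer vector of cluster labels (0-based; -1 = noise), in the
#'   original point order.
#' @export
optics_xi_clusters <- function(opt, xi = 0.05, minPts = 5,
                               min_cluster_size = minPts,
                               extraction = c("maximal", "leaf")) {
  extraction <- match.arg(extraction)
  n <- length(opt$order)
  rplot <- c(opt$reachability[opt$order], Inf)
  pplot <- opt$predecessor[opt$order]
  xic <- 1 - xi
  ratio <- rplot[seq_len(n)] / rplot[seq_len(n) + 1L]
  steep_up <- !is.na(ratio) & ratio <= xic
  steep_down <- !is.na(ratio) & ratio >= 1 / xic
  up <- !is.na(ratio) & ratio < 1
  down <- !is.na(ratio) & ratio > 1

  sdas <- list()
  clusters <- list()
  index <- 1L
  mib <- 0
  while (index <= n) {
    mib <- max(mib, rplot[index])
    if (steep_down[index]) {
      sdas <- filter_sdas(sdas, mib, xic, rplot)
      d_start <- index
      d_end <- extend_region(steep_down, up, index, minPts)
      sdas[[length(sdas) + 1L]] <- list(start = d_start, end = d_end,
                                        mib = 0)
      index <- d_end + 1L
      mib <- rplot[min(index, n + 1L)]
    } else if (steep_up[index]) {
      sdas <- filter_sdas(sdas, mib, xic, rplot)
      u_start <- index
      u_end <- extend_region(steep_up, down, index, minPts)
      index <- u_end + 1L
      mib <- rplot[min(index, n + 1L)]
      for (dd in sdas) {
        c_start <- dd$start
        c_end <- u_end
        # the valley must be deeper than anything between its walls
        if (rplot[c_end + 1L] * xic < dd$mib) next
        d_max <- rplot[dd$start]
        if (d_max * xic >= rplot[c_end + 1L]) {
          while (c_start < dd$end &&
                 rplot[c_start + 1L] > rplot[c_end + 1L])
            c_start <- c_start + 1L
        } else if (rplot[c_end + 1L] * xic >= d_max) {
          while (c_end > u_start && rplot[c_end - 1L] > d_max)
            c_end <- c_end - 1L
        }
        cc <- correct_predecessor(rplot, pplot, opt$order, c_start, c_end)
        if (is.null(cc)) next
        c_start <- cc[1]; c_end <- cc[2]
        if (c_end - c_start + 1L < min_cluster_size) next
        if (c_start > dd$end) next
        if (c_end < u_start) next
        clusters[[length(clusters) + 1L]] <- c(c_start, c_end)
      }
    } else {
      index <- index + 1L
    }
  }
  labels_ord <- rep(-1L, n)
  if (length(clusters)) {
    widths <- vapply(clusters, function(cc) cc[2] - cc[1], numeric(1))
    if (extraction == "maximal" && length(clusters) > 1) {
      # A cluster spanning (nearly) the whole ordering is a container, not a
      # unit — but only when the structure beneath it is genuinely
      # multimodal: at least two disjoint sub-clusters jointly covering most
      # of the ordering. A lone density mode keeps its root cluster.
      full <- vapply(clusters, function(cc) cc[2] - cc[1] + 1L >= n - minPts,
                     logical(1))
      if (any(full) && !all(full)) {
        sub <- clusters[!full]
        sub <- sub[order(-vapply(sub, function(cc) cc[2] - cc[1], numeric(1)))]
        taken <- rep(FALSE, n)
        covered <- 0L
        parts <- 0L
        for (cc in sub) {
          span <- cc[1]:cc[2]
          if (!any(taken[span])) {
            taken[span] <- TRUE
            covered <- covered + length(span)
            parts <- parts + 1L
          }
        }
        if (parts >= 2L && covered >= 0.7 * n) {
          clusters <- clusters[!full]
          widths <- widths[!full]
        }
      }
    }
    ord <- if (extraction == "maximal") order(-widths) else order(widths)
    lab <- 0L
    for (cc in clusters[ord]) {
      span <- cc[1]:cc[2]
      if (all(labels_ord[span] == -1L)) {
        labels_ord[span] <- lab
        lab <- lab + 1L
      }
    }
  }
  labels <- integer(n)
  labels[opt$order] <- labels_ord
  labels
}
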