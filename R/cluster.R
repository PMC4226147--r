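# Cluster-based sign-flip permutation machinery over the
# channel x frequency x time grid.
#
# Adjacency rule: two bins are adjacent iff they share two axes and are
# (a) spatial neighbors on the montage graph, or (b) adjacent frequency
# bins, or (c) adjacent time bins (rook adjacency on the grid, no
# diagonals). Positive and negative supra-threshold bins are clustered
# separately; the cluster statistic is the "mass" (sum of t over member
# bins), and the null distribution is the maximum |mass| over sign-flip
# permutations of the subject-level maps, so the correction controls the
# family-wise error across both signs jointly.

#' Per-subject effect maps on a common grid
#'
#' Container consumed by [cluster_permutation_test()]: one row per subject,
#' one column per grid bin (channel fastest, then frequency, then time).
#'
#' @param maps numeric matrix, subjects x bins.
#' @param channels character vector of channel names (EEG only).
#' @param freqs,times grid axes.
#' @param kind what the maps contain ("diff", "slope", ...).
#' @return Object of class `subject_maps`.
#' @export
subject_maps <- function(maps, channels, freqs, times, kind = "diff") {
  nb <- length(channels) * length(freqs) * length(times)
  stopifnot(is.matrix(maps), ncol(maps) == nb, nrow(maps) >= 1)
  structure(list(maps = maps, channels = as.character(channels),
                 freqs = freqs, times = times, kind = kind),
            class = "subject_maps")
}

#' @export
print.subject_maps <- function(x, ...) {
  cat(sprintf("subject_maps (%s): %d subjects, grid %d ch x %d freq x %d time\n",
              x$kind, nrow(x$maps), length(x$channels), length(x$freqs),
              length(x$times)))
  invisible(x)
}

#' Decode flat bin indices to grid coordinates
#' @param maps a `subject_maps` (or anything with channels/freqs/times).
#' @param bins integer bin indices.
#' @return data.frame with `channel`, `freq`, `time`.
#' @export
decode_bins <- function(maps, bins) {
  nch <- length(maps$channels); nf <- length(maps$freqs)
  b0 <- bins - 1L
  data.frame(
    channel = maps$channels[b0 %% nch + 1L],
    freq = maps$freqs[(b0 %/% nch) %% nf + 1L],
    time = maps$times[b0 %/% (nch * nf) + 1L]
  )
}

#' Flat bin indices of a channel x band x window selection
#' @param maps a `subject_maps`.
#' @param channels channel names.
#' @param band,window closed intervals on the frequency / time axes.
#' @return Integer vector of bin indices.
#' @export
encode_bins <- function(maps, channels, band, window) {
  nch <- length(maps$channels); nf <- length(maps$freqs)
  ci <- match(channels, maps$channels)
  stopifnot(!anyNA(ci))
  fi <- grid_bins(maps$freqs, band)
  ti <- grid_bins(maps$times, window)
  as.vector(outer(outer(ci, (fi - 1L) * nch, "+"),
                  (ti - 1L) * nch * nf, "+"))
}

# edge list (2-column integer matrix of bin indices) of the grid adjacency
grid_edge_list <- function(channels, nf, nt, neighbors) {
  nch <- length(channels)
  off <- function(f, t) nch * ((f - 1L) + nf * (t - 1L))
  # frequency-adjacent bins: same channel and time
  i <- as.vector(outer(seq_len(nch),
                       off(rep(seq_len(nf - 1L), nt),
                           rep(seq_len(nt), each = nf - 1L)), "+"))
  ef <- cbind(i, i + nch)
  # time-adjacent bins: same channel and frequency
  j <- as.vector(outer(seq_len(nch * nf), nch * nf * (seq_len(nt - 1L) - 1L),
                       "+"))
  et <- cbind(j, j + nch * nf)
  # spatially neighboring channels: same frequency and time
  pairs <- do.call(rbind, lapply(seq_along(channels), function(a) {
    nb <- match(neighbors[[channels[a]]], channels)
    nb <- nb[!is.na(nb) & nb > a]
    if (length(nb) == 0) NULL else cbind(a, nb)
  }))
  if (!is.null(pairs) && nrow(pairs) > 0) {
    offs <- as.vector(outer(off(rep(seq_len(nf), nt),
                                rep(seq_len(nt), each = nf)), 0L, "+"))
    ec <- cbind(rep(pairs[, 1], each = length(offs)) + offs,
                rep(pairs[, 2], each = length(offs)) + offs)
  } else {
    ec <- matrix(integer(0), 0, 2)
  }
  e <- rbind(ef, et, ec)
  storage.mode(e) <- "integer"
  e
}

# union-find over supra-threshold bins; returns list(membership, masses)
uf_clusters <- function(nodes, edges, tvals) {
  k <- length(nodes)
  if (k == 0) {
    return(list(members = list(), masses = numeric(0)))
  }
  idx_of <- integer(max(nodes))
  idx_of[nodes] <- seq_len(k)
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges) > 0) {
    for (r in seq_len(nrow(edges))) {
      ra <- find(idx_of[edges[r, 1]])
      rb <- find(idx_of[edges[r, 2]])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  members <- split(nodes, roots)
  masses <- vapply(members, function(b) sum(tvals[b]), numeric(1))
  list(members = unname(members), masses = unname(masses))
}

# clusters of one sign; sign = +1 or -1
signed_clusters <- function(tvals, crit, edges, sign) {
  x <- sign * tvals
  supra <- x > crit & !is.na(x)
  nodes <- which(supra)
  if (length(nodes) == 0) {
    return(list(members = list(), masses = numeric(0)))
  }
  keep <- supra[edges[, 1]] & supra[edges[, 2]]
  uf_clusters(nodes, edges[keep, , drop = FALSE], tvals)
}

# maximum |cluster mass| over both signs (0 if no supra-threshold bin)
max_cluster_mass <- function(tvals, crit, edges) {
  mp <- signed_clusters(tvals, crit, edges, 1)$masses
  mn <- signed_clusters(tvals, crit, edges, -1)$masses
  m <- c(abs(mp), abs(mn))
  if (length(m) == 0) 0 else max(m)
}

# one-sample t across rows of X for arbitrary sign vector s, using the
# sign-invariance of the second moment
signed_tstat <- function(s, X, ss, n) {
  m <- as.vector(s %*% X) / n
  v <- (ss - n * m^2) / (n - 1)
  tt <- m / sqrt(v / n)
  tt[v <= .Machine$double.eps * 100] <- 0
  tt
}

#' Cluster-based sign-flip permutation test
#'
#' Corrects mass-univariate tests over the channel x frequency x time grid
#' for multiple comparisons. The observed statistic is the one-sample t of
#' the subject maps against 0 at every bin (equivalently, the paired t when
#' the maps are condition differences). Bins exceeding the two-tailed
#' critical t at `cluster_alpha` (df = n_subjects − 1) are grouped into
#' connected clusters (spatial neighbor OR adjacent frequency bin OR
#' adjacent time bin), separately per sign, and each cluster is scored by
#' its mass (sum of t). The null distribution of the maximum |mass| is
#' built by randomly flipping the sign of each subject's map — valid for
#' paired contrasts and one-sample slope tests — and each observed
#' cluster's corrected p is `(1 + #{null max >= |mass|}) / (1 + n_perm)`.
#' When `2^n_subjects <= n_perm`, all sign patterns are enumerated instead
#' and p is the exact tail proportion over the full enumeration.
#'
#' @param maps a [subject_maps()].
#' @param neighbors channel neighbor graph ([build_neighbors()]).
#' @param n_perm number of random sign-flip permutations (>= 100).
#' @param cluster_alpha two-tailed per-bin alpha of the cluster-forming
#'   threshold.
#' @param alpha corrected significance level for flagging clusters.
#' @param seed seed for the permutation draws.
#' @return An `eeg_cluster_result`: `clusters` data.frame (`id`, `sign`,
#'   `n_bins`, `mass`, `p`, `significant`), `members` (list of bin index
#'   vectors), the observed t map as an `eeg_statmap`, the cluster-forming
#'   threshold, `n_perm`, `exact` flag, and the null max-mass distribution.
#' @export
cluster_permutation_test <- function(maps, neighbors, n_perm = 1000,
                                     cluster_alpha = 0.05, alpha = 0.05,
                                     seed = NULL) {
  stopifnot(inherits(maps, "subject_maps"),
            n_perm >= 100,
            cluster_alpha > 0, cluster_alpha < 1, alpha > 0, alpha < 1)
  X <- maps$maps
  n <- nrow(X)
  if (n < 2) stop("need at least 2 subjects for the permutation test")
  crit <- stats::qt(1 - cluster_alpha / 2, df = n - 1)
  ss <- colSums(X^2)
  edges <- grid_edge_list(maps$channels, length(maps$freqs),
                          length(maps$times), neighbors)

  tobs <- signed_tstat(rep(1, n), X, ss, n)
  cp <- signed_clusters(tobs, crit, edges, 1)
  cn <- signed_clusters(tobs, crit, edges, -1)
  members <- c(cp$members, cn$members)
  masses <- c(cp$masses, cn$masses)
  signs <- c(rep(1L, length(cp$masses)), rep(-1L, length(cn$masses)))

  exact <- n <= 30 && 2^n <= n_perm
  if (exact) {
    npat <- 2^n
    null_max <- numeric(npat)
    for (p in seq_len(npat)) {
      bits <- as.integer(intToBits(p - 1))[seq_len(n)]
      s <- ifelse(bits == 1L, -1, 1)
      null_max[p] <- max_cluster_mass(signed_tstat(s, X, ss, n), crit, edges)
    }
  } else {
    if (!is.null(seed)) set.seed(seed)
    null_max <- numeric(n_perm)
    for (p in seq_len(n_perm)) {
      s <- sample(c(-1, 1), n, replace = TRUE)
      null_max[p] <- max_cluster_mass(signed_tstat(s, X, ss, n), crit, edges)
    }
  }
  pvals <- if (length(masses) == 0) {
    numeric(0)
  } else if (exact) {
    vapply(abs(masses), function(m) mean(null_max >= m - 1e-12), numeric(1))
  } else {
    vapply(abs(masses), function(m) (1 + sum(null_max >= m - 1e-12)) /
             (1 + length(null_max)), numeric(1))
  }
  ord <- order(abs(masses), decreasing = TRUE)
  clusters <- data.frame(
    id = seq_along(ord),
    sign = signs[ord],
    n_bins = vapply(members[ord], length, integer(1)),
    mass = masses[ord],
    p = pvals[ord],
    significant = pvals[ord] <= alpha
  )
  tmap <- new_statmap(
    array(tobs, dim = c(length(maps$channels), length(maps$freqs),
                        length(maps$times))),
    kind = "t", df = n - 1,
    channels = data.frame(name = maps$channels, type = "EEG",
                          stringsAsFactors = FALSE),
    freqs = maps$freqs, times = maps$times)
  structure(
    list(clusters = clusters, members = members[ord], tmap = tmap,
         cluster_threshold = crit, cluster_alpha = cluster_alpha,
         alpha = alpha, n_perm = if (exact) length(null_max) else n_perm,
         exact = exact,
         null_max_summary = stats::quantile(null_max,
                                            c(0.5, 0.9, 0.95, 0.99)),
         null_max = null_max,
         grid = maps[c("channels", "freqs", "times")]),
    class = "eeg_cluster_result"
  )
}

#' @export
print.eeg_cluster_result <- function(x, ...) {
  cat(sprintf(
    "cluster permutation test: %d cluster(s), threshold |t| > %.3f, %s%d permutations\n",
    nrow(x$clusters), x$cluster_threshold,
    if (x$exact) "exact enumeration of " else "", x$n_perm))
  if (nrow(x$clusters) == 0) {
    cat("  no supra-threshold clusters\n")
  } else {
    print(x$clusters, row.names = FALSE)
  }
  invisible(x)
}

#' Export a cluster result as JSON plus a TSV of bin memberships
#'
#' @param result an `eeg_cluster_result`.
#' @param stub output path stub; writes `<stub>.json` and `<stub>_bins.tsv`.
#' @export
write_cluster_result <- function(result, stub) {
  jsonlite::write_json(
    list(clusters = result$clusters,
         cluster_threshold = result$cluster_threshold,
         n_perm = result$n_perm, exact = result$exact,
         alpha = result$alpha,
         null_max_quantiles = as.list(result$null_max_summary)),
    paste0(stub, ".json"), auto_unbox = TRUE, digits = NA)
  bins <- do.call(rbind, lapply(seq_along(result$members), function(i) {
    g <- result$grid
    d <- decode_bins(list(channels = g$channels, freqs = g$freqs,
                          times = g$times), result$members[[i]])
    cbind(cluster = result$clusters$id[i], d)
  }))
  if (is.null(bins)) {
    bins <- data.frame(cluster = integer(0), channel = character(0),
                       freq = numeric(0), time = numeric(0))
  }
  utils::write.table(bins, paste0(stub, "_bins.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(stub)
}
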