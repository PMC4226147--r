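#' Reject trials by peak-to-peak amplitude
#'
#' Deterministic surrogate for visual trial rejection: a trial is removed
#' iff the peak-to-peak amplitude of any EEG channel exceeds `limit`. The
#' EOG channel is ignored (ocular activity is handled by
#' [remove_ocular_components()]). Applied to the whole session irrespective
#' of condition; the order of surviving trials is preserved.
#'
#' @param epochs an `eeg_epochs`.
#' @param limit peak-to-peak limit in µV (default 200).
#' @return List with the surviving `epochs` and a `rejection_log`
#'   (data.frame `trial`, `reason` plus a `counts` attribute).
#' @export
reject_by_amplitude <- function(epochs, limit = 200) {
  stopifnot(inherits(epochs, "eeg_epochs"), limit > 0)
  eeg <- eeg_channel_idx(epochs)
  ntrial <- dim(epochs$data)[1]
  p2p <- vapply(seq_len(ntrial), function(tr) {
    x <- epochs$data[tr, eeg, , drop = FALSE]
    max(apply(x[1, , , drop = TRUE], 1, function(v) max(v) - min(v)))
  }, numeric(1))
  bad <- which(p2p > limit)
  log <- rejection_log(
    data.frame(trial = bad,
               reason = rep("amplitude", length(bad)),
               stringsAsFactors = FALSE),
    n_in = ntrial, n_out = ntrial - length(bad))
  if (length(bad) == ntrial) {
    warning("all trials exceeded the amplitude limit; result is empty")
  }
  keep <- setdiff(seq_len(ntrial), bad)
  arts <- NULL
  if (!is.null(epochs$artifacts)) {
    arts <- epochs$artifacts[epochs$artifacts$trial %in% keep, , drop = FALSE]
    arts$trial <- match(arts$trial, keep)   # renumber to surviving trials
  }
  out <- new_epochs(epochs$data[keep, , , drop = FALSE], epochs$fs,
                    epochs$t0, epochs$channels, epochs$labels[keep],
                    epochs$subject, artifacts = arts)
  list(epochs = out, log = log)
}

rejection_log <- function(df, n_in, n_out, components = NULL) {
  structure(list(rejected = df, n_in = n_in, n_out = n_out,
                 components = components),
            class = "rejection_log")
}

#' @export
print.rejection_log <- function(x, ...) {
  cat(sprintf("rejection_log: %d -> %d trials (%d removed)\n",
              x$n_in, x$n_out, nrow(x$rejected)))
  if (!is.null(x$components) && nrow(x$components) > 0) {
    cat("  components removed:",
        paste(sprintf("#%d (r=%.2f)", x$components$component,
                      x$components$eog_correlation), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a rejection log as JSON
#' @param log a `rejection_log`.
#' @param path output path.
#' @export
write_rejection_log <- function(log, path) {
  jsonlite::write_json(
    list(n_in = log$n_in, n_out = log$n_out,
         rejected = log$rejected, components = log$components),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Remove EOG-correlated principal components
#'
#' Objective stand-in for visual component selection: a principal component
#' analysis is computed over the concatenated EEG epochs (whole epochs, all
#' trials, condition-blind) and every component whose time course correlates
#' with the EOG channel at `|r| >= corr_threshold` is projected out of the
#' data. Rank of the output covariance drops by the number of removed
#' components. Removal is iterated (PCA recomputed on the cleaned data)
#' until no remaining component reaches the threshold, so the operation is
#' idempotent at a fixed threshold. If no component exceeds the threshold,
#' the data are returned unchanged and the log says so.
#'
#' @param epochs an `eeg_epochs` containing the EOG channel.
#' @param eog_channel name of the EOG channel.
#' @param corr_threshold absolute Pearson correlation above which a
#'   component is considered ocular (0 < threshold < 1; default 0.7).
#' @return List with cleaned `epochs` (EOG channel carried through
#'   untouched) and a `rejection_log` whose `components` table holds the
#'   removed component indices and their EOG correlations.
#' @export
remove_ocular_components <- function(epochs, eog_channel = "EOG",
                                     corr_threshold = 0.7) {
  stopifnot(inherits(epochs, "eeg_epochs"),
            corr_threshold > 0, corr_threshold < 1)
  eog_i <- match(eog_channel, epochs$channels$name)
  if (is.na(eog_i)) stop("EOG channel '", eog_channel, "' not present")
  eeg <- eeg_channel_idx(epochs)
  d <- dim(epochs$data)
  # concatenate epochs: (trial*sample) x channel
  X <- matrix(aperm(epochs$data[, eeg, , drop = FALSE], c(3, 1, 2)),
              d[1] * d[3], length(eeg))
  eogv <- as.vector(aperm(epochs$data[, eog_i, , drop = FALSE], c(3, 1, 2)))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  comp <- data.frame(pass = integer(0), component = integer(0),
                     eog_correlation = numeric(0))
  removed <- 0L
  for (pass in seq_len(length(eeg))) {
    eg <- eigen(crossprod(Xc) / (nrow(Xc) - 1), symmetric = TRUE)
    V <- eg$vectors
    scores <- Xc %*% V
    r <- suppressWarnings(as.vector(stats::cor(scores, eogv)))
    r[is.na(r)] <- 0
    # null-space directions (already projected out) carry only numerical
    # noise; never select them
    r[eg$values <= max(eg$values) * 1e-10] <- 0
    bad <- which(abs(r) >= corr_threshold)
    if (length(bad) == 0) break
    comp <- rbind(comp, data.frame(pass = pass, component = bad,
                                   eog_correlation = r[bad]))
    removed <- removed + length(bad)
    Xc <- Xc - scores[, bad, drop = FALSE] %*% t(V[, bad, drop = FALSE])
  }
  log <- rejection_log(
    data.frame(trial = integer(0), reason = character(0),
               stringsAsFactors = FALSE),
    n_in = d[1], n_out = d[1], components = comp)
  if (removed == 0L) {
    return(list(epochs = epochs, log = log))
  }
  Xclean <- sweep(Xc, 2, mu, "+")
  out <- epochs
  out$data[, eeg, ] <- aperm(array(Xclean, dim = c(d[3], d[1], length(eeg))),
                             c(2, 3, 1))
  list(epochs = out, log = log)
}
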