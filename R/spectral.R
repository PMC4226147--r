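#' Hanning-taper time-frequency decomposition
#'
#' Sliding-window Fourier power on the fixed analysis grid: a Hann taper of
#' `window_length` seconds (default 0.4 s), frequencies 2 to 48 Hz in steps
#' of 2 Hz (24 bins), window centers stepped by `t_step` (default 0.1 s)
#' across the part of the epoch where a full window fits. Per trial and
#' channel, the power at frequency f and center t is
#' `2 * |sum_n h[n] x[n] exp(-i 2 pi f n / fs)|^2 / (sum_n h[n])^2`,
#' i.e. amplitude-consistent normalization: a pure sinusoid of amplitude A
#' at a grid frequency yields power A^2 / 2 — its variance. The constant is
#' immaterial downstream (all statistics are contrasts or ratios) but is
#' stated here and held fixed across all bins.
#'
#' The EOG channel is excluded; only EEG channels enter the TFR.
#'
#' @param epochs an `eeg_epochs`.
#' @param freqs analysis frequencies, Hz (default `seq(2, 48, by = 2)`).
#' @param t_step spacing of window centers in seconds; `t_step * fs` must be
#'   an integer number of samples.
#' @param window_length taper length in seconds.
#' @return An `eeg_tfr`: list with `power` (trial x channel x frequency x
#'   time, µV²), `freqs`, `times` (window centers, s), `channels`, `labels`,
#'   `subject`, `window_length`, `fs`.
#' @export
tfr_hanning <- function(epochs, freqs = seq(2, 48, by = 2),
                        t_step = 0.1, window_length = 0.4) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (max(freqs) > epochs$fs / 2) {
    stop("configuration error: max analysis frequency ", max(freqs),
         " Hz exceeds the Nyquist frequency ", epochs$fs / 2, " Hz")
  }
  fs <- epochs$fs
  step <- t_step * fs
  if (abs(step - round(step)) > 1e-9) {
    stop("configuration error: t_step must be an integer number of samples")
  }
  step <- as.integer(round(step))
  nwin <- as.integer(round(window_length * fs)) + 1L  # odd, symmetric taper
  if (nwin %% 2 == 0) nwin <- nwin + 1L
  half <- (nwin - 1L) %/% 2L
  d <- dim(epochs$data)
  if (d[3] < nwin) stop("epoch too short for one analysis window")
  eeg <- eeg_channel_idx(epochs)
  nch <- length(eeg)
  ntrial <- d[1]

  # window centers on the sample grid, aligned to multiples of t_step
  tax <- epoch_times(epochs)
  first <- half + 1L
  last <- d[3] - half
  cand <- seq(first, last)
  # snap to centers whose time is a multiple of t_step (relative to onset)
  keep <- abs((tax[cand] / t_step) - round(tax[cand] / t_step)) < 1e-9
  centers <- cand[keep][seq(1, sum(keep), by = 1)]
  centers <- centers[seq(1, length(centers))]
  # enforce the step between successive centers
  centers <- centers[((centers - centers[1]) %% step) == 0]
  if (length(centers) == 0) stop("no valid window centers on the time grid")
  times <- tax[centers]

  tau <- (-half:half) / fs
  h <- 0.5 * (1 - cos(2 * pi * (0:(nwin - 1)) / (nwin - 1)))  # Hann taper
  hsum <- sum(h)
  Cb <- (h * cos(2 * pi * outer(tau, freqs))) # nwin x nf
  Sb <- (h * sin(2 * pi * outer(tau, freqs)))

  power <- array(0, dim = c(ntrial, nch, length(freqs), length(times)))
  for (ti in seq_along(centers)) {
    idx <- (centers[ti] - half):(centers[ti] + half)
    seg <- matrix(epochs$data[, eeg, idx, drop = FALSE],
                  ntrial * nch, nwin)
    re <- seg %*% Cb
    im <- seg %*% Sb
    power[, , , ti] <- array(2 * (re^2 + im^2) / hsum^2,
                             dim = c(ntrial, nch, length(freqs)))
  }
  structure(
    list(power = power, freqs = freqs, times = times,
         channels = epochs$channels[eeg, , drop = FALSE],
         labels = epochs$labels, subject = epochs$subject,
         window_length = window_length, fs = fs),
    class = "eeg_tfr"
  )
}

#' @export
print.eeg_tfr <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf(
    "eeg_tfr: %d trials x %d channels x %d freqs (%g-%g Hz) x %d times (%g to %g s)\n",
    d[1], d[2], d[3], min(x$freqs), max(x$freqs), d[4],
    min(x$times), max(x$times)))
  invisible(x)
}

#' Baseline-referenced ERS/ERD t-map
#'
#' For every channel x frequency x time bin, the dependent-samples t across
#' trials of (bin power − that trial's mean baseline power at the same
#' channel and frequency), df = n_trials − 1. Negative t indicates
#' event-related desynchronization (power below baseline), positive t
#' synchronization. Bins with zero variance of the differences are flagged
#' undefined (NA) and excluded from downstream cluster maxima.
#'
#' @param tfr an `eeg_tfr`.
#' @param baseline baseline interval in seconds (closed; default
#'   `c(-0.4, -0.2)`).
#' @return An `eeg_statmap` (`values` channel x frequency x time, `kind`
#'   "t", `df`).
#' @export
ers_erd_tmap <- function(tfr, baseline = c(-0.4, -0.2)) {
  stopifnot(inherits(tfr, "eeg_tfr"))
  d <- dim(tfr$power)
  if (d[1] < 2) stop("need at least 2 trials for the ERS/ERD t-map")
  bidx <- which(tfr$times >= baseline[1] & tfr$times <= baseline[2])
  if (length(bidx) == 0) stop("no time bins inside the baseline interval")
  pb <- tfr$power[, , , bidx, drop = FALSE]
  b <- array(rowMeans(matrix(pb, d[1] * d[2] * d[3], length(bidx))),
             dim = d[1:3])
  dif <- tfr$power - as.vector(b)  # recycles baseline along the time axis
  n <- d[1]
  M <- matrix(dif, n, d[2] * d[3] * d[4])
  m <- colMeans(M)
  v <- (colSums(M^2) - n * m^2) / (n - 1)
  tt <- m / sqrt(v / n)
  tt[v <= .Machine$double.eps * 100] <- NA_real_
  new_statmap(array(tt, dim = d[2:4]), kind = "t", df = n - 1,
              channels = tfr$channels, freqs = tfr$freqs, times = tfr$times)
}

#' Statistic map on the channel x frequency x time grid
#'
#' @param values numeric array channel x frequency x time.
#' @param kind statistic kind, e.g. "t", "slope", "mean-t", "power".
#' @param df degrees of freedom, if applicable.
#' @param channels channel table (EEG channels only).
#' @param freqs,times grid axes.
#' @return An `eeg_statmap`.
#' @export
new_statmap <- function(values, kind, df = NA_real_, channels, freqs, times) {
  stopifnot(is.array(values), length(dim(values)) == 3,
            dim(values)[1] == nrow(channels),
            dim(values)[2] == length(freqs),
            dim(values)[3] == length(times))
  structure(list(values = values, kind = kind, df = df,
                 channels = channels, freqs = freqs, times = times),
            class = "eeg_statmap")
}

#' @export
print.eeg_statmap <- function(x, ...) {
  cat(sprintf("eeg_statmap (%s, df=%s): %d channels x %d freqs x %d times; range [%.3g, %.3g]\n",
              x$kind, format(x$df), dim(x$values)[1], dim(x$values)[2],
              dim(x$values)[3],
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

# moving average along one margin of the last two axes, truncated kernels
# renormalized to the available bins
smooth_margin <- function(arr, margin, k) {
  d <- dim(arr)
  L <- d[margin]
  if (k > L) stop("smoothing kernel larger than axis length ", L)
  if (k == 1) return(arr)
  h <- (k - 1) %/% 2
  perm <- c(margin, setdiff(seq_along(d), margin))
  A <- aperm(arr, perm)
  M <- matrix(A, L, prod(d[-margin]))
  cs <- rbind(0, apply(M, 2, cumsum))
  lo <- pmax(seq_len(L) - h, 1)
  hi <- pmin(seq_len(L) + h, L)
  S <- cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]
  S <- S / (hi - lo + 1)
  out <- array(S, dim = d[perm])
  aperm(out, order(perm))
}

#' Boxcar smoothing over the time and frequency axes
#'
#' Moving average over `n_freq_bins` x `n_time_bins` (default 3 x 3 = 6 Hz
#' x 0.3 s on the standard grid), applied per channel (and per trial for a
#' TFR). The kernel is separable; at the axis edges the kernel is truncated
#' and renormalized to the bins actually available, so a constant map is
#' preserved everywhere and power never becomes negative.
#'
#' @param x an `eeg_tfr` or `eeg_statmap`.
#' @param n_time_bins,n_freq_bins odd kernel lengths in bins.
#' @return Same type as `x`.
#' @export
boxcar_smooth <- function(x, n_time_bins = 3, n_freq_bins = 3) {
  stopifnot(n_time_bins >= 1, n_freq_bins >= 1,
            n_time_bins %% 2 == 1, n_freq_bins %% 2 == 1)
  if (inherits(x, "eeg_tfr")) {
    x$power <- smooth_margin(smooth_margin(x$power, 3, n_freq_bins),
                             4, n_time_bins)
    x
  } else if (inherits(x, "eeg_statmap")) {
    x$values <- smooth_margin(smooth_margin(x$values, 2, n_freq_bins),
                              3, n_time_bins)
    x
  } else {
    stop("boxcar_smooth expects an eeg_tfr or eeg_statmap")
  }
}

#' Select grid bins inside closed band / window intervals
#' @keywords internal
grid_bins <- function(axis, interval) {
  which(axis >= interval[1] - 1e-9 & axis <= interval[2] + 1e-9)
}

#' Band-limited power features
#'
#' Power averaged over the grid bins whose frequency center lies in the
#' closed `band` interval and whose time center lies in the closed `window`
#' interval (so band 26-30 Hz on the 2 Hz grid pools bins {26, 28, 30}, and
#' the non-grid label 10.5-14.5 Hz pools bins {12, 14}). Returns one value
#' per trial and channel, or one pooled value per trial.
#'
#' @param tfr an `eeg_tfr`.
#' @param band frequency interval, Hz.
#' @param window time interval, s.
#' @param channels channel names to include (default: all EEG channels).
#' @param pool_channels if TRUE, additionally average over channels.
#' @param log if TRUE, return log power (features for decoding).
#' @return Matrix trials x channels (named columns), or a vector if
#'   `pool_channels = TRUE`.
#' @export
band_power <- function(tfr, band, window, channels = NULL,
                       pool_channels = FALSE, log = FALSE) {
  stopifnot(inherits(tfr, "eeg_tfr"))
  fb <- grid_bins(tfr$freqs, band)
  tb <- grid_bins(tfr$times, window)
  if (length(fb) == 0 || length(tb) == 0) {
    stop("empty bin selection: band/window do not intersect the grid")
  }
  if (is.null(channels)) channels <- tfr$channels$name
  ci <- match(channels, tfr$channels$name)
  if (anyNA(ci)) {
    stop("unknown channel(s): ",
         paste(channels[is.na(ci)], collapse = ", "))
  }
  d <- dim(tfr$power)
  sub <- tfr$power[, ci, fb, tb, drop = FALSE]
  m <- matrix(sub, d[1] * length(ci), length(fb) * length(tb))
  feat <- matrix(rowMeans(m), d[1], length(ci))
  colnames(feat) <- channels
  if (log) feat <- base::log(feat)
  if (pool_channels) rowMeans(feat) else feat
}

# ---------------------------------------------------------------------------
# TFR serialization, same JSON + float32 binary scheme as epochs

#' Write / read a TFR in the portable JSON + binary format
#'
#' `<stub>.tfr.json` records the axes and provenance; `<stub>.tfr.bin` holds
#' the power array as float32 little-endian in
#' `[trial][channel][frequency][time]` order.
#'
#' @param tfr an `eeg_tfr`.
#' @param path path stub.
#' @return `read_tfr` returns an `eeg_tfr`.
#' @export
write_tfr <- function(tfr, path) {
  stopifnot(inherits(tfr, "eeg_tfr"))
  stub <- strip_stub(path, "tfr")
  header <- list(format_version = EPOCHS_FORMAT_VERSION,
                 freqs = tfr$freqs, times = tfr$times,
                 channels = tfr$channels, labels = tfr$labels,
                 subject = tfr$subject, window_length = tfr$window_length,
                 fs = tfr$fs, dtype = "float32",
                 byte_order = "little-endian", shape = dim(tfr$power))
  jsonlite::write_json(header, paste0(stub, ".tfr.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(paste0(stub, ".tfr.bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(aperm(tfr$power, c(4, 3, 2, 1))), con,
           size = 4L, endian = "little")
  invisible(stub)
}

#' @rdname write_tfr
#' @export
read_tfr <- function(path) {
  stub <- strip_stub(path, "tfr")
  hpath <- paste0(stub, ".tfr.json")
  bpath <- paste0(stub, ".tfr.bin")
  if (!file.exists(hpath) || !file.exists(bpath)) {
    stop("format error: missing header or payload for ", stub)
  }
  h <- jsonlite::read_json(hpath, simplifyVector = TRUE)
  if (is.null(h$format_version) ||
      h$format_version != EPOCHS_FORMAT_VERSION) {
    stop("format error: unknown TFR format version")
  }
  shape <- as.integer(h$shape)
  n <- prod(shape)
  if (file.info(bpath)$size != 4 * n) {
    stop("format error: payload size inconsistent with header shape")
  }
  con <- file(bpath, "rb")
  on.exit(close(con))
  v <- readBin(con, what = "numeric", n = n, size = 4L, endian = "little")
  structure(
    list(power = aperm(array(v, dim = rev(shape)), c(4, 3, 2, 1)),
         freqs = h$freqs, times = h$times,
         channels = as.data.frame(h$channels),
         labels = as.character(h$labels),
         subject = if (is.null(h$subject)) NA_character_ else h$subject,
         window_length = h$window_length, fs = h$fs),
    class = "eeg_tfr"
  )
}
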