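#' Construct an epoched EEG container
#'
#' The unit of all downstream computation: a trial x channel x sample
#' voltage array (µV) with its sampling rate, time origin, channel table and
#' per-trial condition labels.
#'
#' @param data numeric array `[trial, channel, sample]`, µV.
#' @param fs sampling rate, Hz.
#' @param t0 time of the first sample in seconds relative to stimulus onset.
#' @param channels data.frame with columns `name` (unique) and `type`
#'   (`"EEG"` or `"EOG"`), one row per channel.
#' @param labels character vector of per-trial condition labels.
#' @param subject subject identifier.
#' @param artifacts optional ground-truth artifact log (generator output).
#' @return Object of class `eeg_epochs`.
#' @export
new_epochs <- function(data, fs, t0, channels, labels,
                       subject = NA_character_, artifacts = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3, fs > 0)
  stopifnot(is.data.frame(channels), all(c("name", "type") %in% names(channels)))
  if (anyDuplicated(channels$name)) stop("channel names must be unique")
  if (dim(data)[2] != nrow(channels)) {
    stop("data has ", dim(data)[2], " channels but channel table has ",
         nrow(channels))
  }
  if (dim(data)[1] != length(labels)) {
    stop("data has ", dim(data)[1], " trials but ", length(labels), " labels")
  }
  structure(
    list(data = data, fs = fs, t0 = t0,
         channels = channels[, c("name", "type")],
         labels = as.character(labels), subject = subject,
         artifacts = artifacts),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("eeg_epochs: %d trials x %d channels x %d samples (fs %g Hz, t0 %g s)\n",
              d[1], d[2], d[3], x$fs, x$t0))
  if (!is.na(x$subject)) cat("  subject:", x$subject, "\n")
  cat("  labels:", paste(sprintf("%s (%d)", names(table(x$labels)),
                                 table(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

#' Time axis of an epochs object
#' @param epochs an `eeg_epochs`.
#' @return Numeric vector of sample times in seconds.
#' @export
epoch_times <- function(epochs) {
  epochs$t0 + (seq_len(dim(epochs$data)[3]) - 1) / epochs$fs
}

#' Indices of EEG (non-EOG) channels
#' @param epochs an `eeg_epochs`.
#' @return Integer vector.
#' @keywords internal
eeg_channel_idx <- function(epochs) which(epochs$channels$type == "EEG")

#' Cut epochs out of a continuous recording
#'
#' One trial per event, spanning `window` (inclusive endpoints:
#' `diff(window) * fs + 1` samples). Events whose window does not fit inside
#' the recording are skipped with a warning and recorded in the
#' `skipped_events` attribute.
#'
#' @param raw channel x sample matrix of the continuous recording, µV.
#' @param events integer sample indices of stimulus onsets (1-based).
#' @param fs sampling rate, Hz.
#' @param window epoch limits in seconds relative to each event.
#' @param channels channel table (`name`, `type`); defaults to generic names.
#' @param labels optional per-event condition labels, carried through in
#'   event order.
#' @param subject subject identifier.
#' @return An `eeg_epochs` with trials ordered by event time.
#' @export
epoch_continuous <- function(raw, events, fs, window = c(-1, 2),
                             channels = NULL, labels = NULL,
                             subject = NA_character_) {
  stopifnot(is.matrix(raw), fs > 0, length(window) == 2,
            window[1] < window[2])
  if (is.null(channels)) {
    channels <- data.frame(name = paste0("ch", seq_len(nrow(raw))),
                           type = "EEG", stringsAsFactors = FALSE)
  }
  events <- as.integer(events)
  if (is.null(labels)) labels <- rep(NA_character_, length(events))
  stopifnot(length(labels) == length(events))
  ord <- order(events)
  events <- events[ord]
  labels <- labels[ord]
  off0 <- round(window[1] * fs)
  off1 <- round(window[2] * fs)
  nsamp <- off1 - off0 + 1L
  ok <- events + off0 >= 1L & events + off1 <= ncol(raw)
  if (any(!ok)) {
    warning(sum(!ok), " event(s) too close to the recording edge: skipped")
  }
  kept <- which(ok)
  data <- array(0, dim = c(length(kept), nrow(raw), nsamp))
  for (i in seq_along(kept)) {
    e <- events[kept[i]]
    data[i, , ] <- raw[, (e + off0):(e + off1)]
  }
  ep <- new_epochs(data, fs = fs, t0 = off0 / fs, channels = channels,
                   labels = labels[kept], subject = subject)
  attr(ep, "skipped_events") <- events[!ok]
  ep
}

# ---------------------------------------------------------------------------
# Portable on-disk format: <stub>.epochs.json header + <stub>.epochs.bin
# payload, float32 little-endian, trial-major [trial][channel][sample].

EPOCHS_FORMAT_VERSION <- 1L

strip_stub <- function(path, kind) {
  sub(sprintf("\\.%s\\.(json|bin)$", kind), "", path)
}

#' Write / read epochs in the portable JSON + binary format
#'
#' `write_epochs(e, "x")` produces `x.epochs.json` (format version, fs, t0,
#' channel table, trial labels, dtype, byte order, array shape) and
#' `x.epochs.bin` (float32 little-endian payload in `[trial][channel][sample]`
#' order). The round trip is bit-exact at float32 precision. Header/payload
#' inconsistencies and unknown format versions raise a format error.
#'
#' @param epochs an `eeg_epochs`.
#' @param path path stub; the `.epochs.json`/`.epochs.bin` suffixes are
#'   appended (and stripped if already present).
#' @return `write_epochs` invisibly returns the stub; `read_epochs` returns
#'   an `eeg_epochs`.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  stub <- strip_stub(path, "epochs")
  header <- list(
    format_version = EPOCHS_FORMAT_VERSION,
    fs = epochs$fs, t0 = epochs$t0,
    channels = epochs$channels,
    labels = epochs$labels,
    subject = epochs$subject,
    dtype = "float32", byte_order = "little-endian",
    shape = dim(epochs$data)
  )
  jsonlite::write_json(header, paste0(stub, ".epochs.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(paste0(stub, ".epochs.bin"), "wb")
  on.exit(close(con))
  # [trial][channel][sample] nesting = sample fastest: permute to
  # (sample, channel, trial) so column-major flattening gives that order
  writeBin(as.numeric(aperm(epochs$data, c(3, 2, 1))), con,
           size = 4L, endian = "little")
  invisible(stub)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  stub <- strip_stub(path, "epochs")
  hpath <- paste0(stub, ".epochs.json")
  bpath <- paste0(stub, ".epochs.bin")
  if (!file.exists(hpath) || !file.exists(bpath)) {
    stop("format error: missing header or payload for ", stub)
  }
  h <- jsonlite::read_json(hpath, simplifyVector = TRUE)
  if (is.null(h$format_version) ||
      h$format_version != EPOCHS_FORMAT_VERSION) {
    stop("format error: unknown epochs format version: ",
         format(h$format_version))
  }
  shape <- as.integer(h$shape)
  if (length(shape) != 3) stop("format error: shape must have 3 entries")
  n <- prod(shape)
  expected_bytes <- 4 * n
  if (file.info(bpath)$size != expected_bytes) {
    stop(sprintf(
      "format error: payload has %d bytes, header implies %d",
      file.info(bpath)$size, expected_bytes))
  }
  con <- file(bpath, "rb")
  on.exit(close(con))
  v <- readBin(con, what = "numeric", n = n, size = 4L, endian = "little")
  data <- aperm(array(v, dim = rev(shape)), c(3, 2, 1))
  new_epochs(data, fs = h$fs, t0 = h$t0,
             channels = as.data.frame(h$channels),
             labels = as.character(h$labels),
             subject = if (is.null(h$subject)) NA_character_ else h$subject)
}
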