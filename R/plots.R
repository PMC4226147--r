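#' Plot a time-frequency map for one channel
#'
#' Basic image of an `eeg_statmap` slice (frequency x time) for a single
#' channel, with a symmetric color scale for signed statistics.
#'
#' @param statmap an `eeg_statmap`.
#' @param channel channel name.
#' @param file optional PNG path; if given, the plot is written there.
#' @param ... passed to [graphics::image()].
#' @export
plot_statmap_tfr <- function(statmap, channel, file = NULL, ...) {
  ci <- match(channel, statmap$channels$name)
  if (is.na(ci)) stop("unknown channel: ", channel)
  z <- t(statmap$values[ci, , ])   # time x freq for image()
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 600)
    on.exit(grDevices::dev.off())
  }
  lim <- max(abs(z), na.rm = TRUE)
  graphics::image(statmap$times, statmap$freqs, z,
                  zlim = c(-lim, lim),
                  col = grDevices::hcl.colors(64, "Blue-Red 3"),
                  xlab = "time (s)", ylab = "frequency (Hz)",
                  main = sprintf("%s (%s)", channel, statmap$kind), ...)
  graphics::abline(v = 0, lty = 2)
  invisible(statmap)
}

#' Topographic map of a statistic averaged over a band and window
#'
#' Schematic top view: electrodes at their projected montage positions,
#' colored by the statistic averaged over the closed band x window
#' selection.
#'
#' @param statmap an `eeg_statmap`.
#' @param band,window frequency (Hz) and time (s) intervals to average.
#' @param montage electrode table for positions.
#' @param file optional PNG path.
#' @export
plot_topography <- function(statmap, band, window,
                            montage = montage_1020(), file = NULL) {
  fi <- grid_bins(statmap$freqs, band)
  ti <- grid_bins(statmap$times, window)
  if (length(fi) == 0 || length(ti) == 0) stop("empty band/window selection")
  v <- apply(statmap$values[, fi, ti, drop = FALSE], 1, mean, na.rm = TRUE)
  m <- montage[match(statmap$channels$name, montage$name), ]
  # azimuthal equidistant projection to 2D
  th <- acos(pmin(1, pmax(-1, m$z)))
  az <- atan2(m$x, m$y)
  px <- th * sin(az); py <- th * cos(az)
  if (!is.null(file)) {
    grDevices::png(file, width = 700, height = 700)
    on.exit(grDevices::dev.off())
  }
  lim <- max(abs(v), na.rm = TRUE)
  cols <- grDevices::hcl.colors(64, "Blue-Red 3")
  idx <- pmax(1, pmin(64, round((v + lim) / (2 * lim) * 63) + 1))
  graphics::plot(px, py, pch = 21, cex = 3, bg = cols[idx], asp = 1,
                 axes = FALSE, xlab = "", ylab = "",
                 main = sprintf("%g-%g Hz, %g-%g s", band[1], band[2],
                                window[1], window[2]))
  graphics::text(px, py - 0.18, statmap$channels$name, cex = 0.6)
  invisible(v)
}
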