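#' Standard 10-20 montage for the 32-channel recording layout
#'
#' Electrode positions for the 31 scalp channels plus one vertical EOG
#' channel used throughout the package. Positions are constructed on a unit
#' sphere from the classical 10-20 schematic: each electrode is assigned a
#' planar position on the row/column grid of the extended 10-20 system
#' (18 degrees per 10% step) and mapped to the sphere by azimuthal
#' equidistant projection (inclination = planar radius). The inferior
#' temporo-parietal electrodes (TP9/TP10, PO10) sit on the equator, 10%
#' below the outer ring, and the EOG electrode below the right eye.
#'
#' Coordinates are schematic standard positions, adequate for neighbor
#' graphs and topographic display; they are not digitized head-shape
#' coordinates.
#'
#' @return A data.frame with columns `name`, `type` ("EEG" or "EOG") and
#'   unit-sphere coordinates `x` (towards the right ear), `y` (towards the
#'   nasion) and `z` (towards the vertex).
#' @examples
#' m <- montage_1020()
#' subset(m, name == "C3")
#' @export
montage_1020 <- function() {
  # (row, col) on the 10-20 schematic grid; one step = 18 degrees.
  grid <- rbind(
    Fp1 = c(4, -1), Fp2 = c(4, 1),
    F7 = c(2, -4), F3 = c(2, -2), Fz = c(2, 0), F4 = c(2, 2), F8 = c(2, 4),
    FC5 = c(1, -3), FC1 = c(1, -1), FC2 = c(1, 1), FC6 = c(1, 3),
    T7 = c(0, -4), C3 = c(0, -2), Cz = c(0, 0), C4 = c(0, 2), T8 = c(0, 4),
    CP5 = c(-1, -3), CP1 = c(-1, -1), CP2 = c(-1, 1), CP6 = c(-1, 3),
    P7 = c(-2, -4), P3 = c(-2, -2), Pz = c(-2, 0), P4 = c(-2, 2),
    P8 = c(-2, 4),
    O1 = c(-4, -1), Oz = c(-4, 0), O2 = c(-4, 1)
  )
  px <- grid[, 2] * 18  # degrees towards the right
  py <- grid[, 1] * 18  # degrees towards the front
  theta <- sqrt(px^2 + py^2)          # inclination from the vertex
  phi <- atan2(px, py) * 180 / pi     # azimuth from the nasion, + = right
  # electrodes below the outer ring, plus the infra-orbital EOG electrode
  extra <- rbind(
    TP9 = c(90, -108), TP10 = c(90, 108), PO10 = c(90, 144),
    EOG = c(112, 18)
  )
  name <- c(rownames(grid), rownames(extra))
  theta <- c(theta, extra[, 1])
  phi <- c(phi, extra[, 2])
  # canonical front-to-back channel order
  ord <- c(
    "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
    "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
    "P7", "P3", "Pz", "P4", "P8", "PO10", "O1", "Oz", "O2", "EOG"
  )
  i <- match(ord, name)
  th <- theta[i] * pi / 180
  ph <- phi[i] * pi / 180
  data.frame(
    name = ord,
    type = ifelse(ord == "EOG", "EOG", "EEG"),
    x = sin(th) * sin(ph),
    y = sin(th) * cos(ph),
    z = cos(th),
    stringsAsFactors = FALSE
  )
}

#' Great-circle distances between montage electrodes
#'
#' @param montage data.frame as returned by [montage_1020()].
#' @return Symmetric matrix of angular distances in degrees.
#' @keywords internal
montage_distances <- function(montage) {
  xyz <- as.matrix(montage[, c("x", "y", "z")])
  d <- tcrossprod(xyz)
  d[d > 1] <- 1
  d[d < -1] <- -1
  acos(d) * 180 / pi
}

#' Build a channel neighbor graph from electrode positions
#'
#' Two scalp channels are neighbors iff their great-circle distance on the
#' unit sphere is positive and at most `angular_threshold`. The EOG channel
#' is excluded: it never participates in topographic statistics. The default
#' threshold of 40 degrees links each electrode of the 10-20 grid to its
#' surrounding ring (for C3: FC1, FC5, CP1, CP5, Cz, T7, F3, P3) and yields
#' a connected graph on the standard montage.
#'
#' @param montage data.frame of electrode positions ([montage_1020()]).
#' @param angular_threshold maximum angular distance in degrees.
#' @return Named list: for each EEG channel, the character vector of its
#'   neighbors. The relation is symmetric and irreflexive by construction.
#' @export
build_neighbors <- function(montage = montage_1020(), angular_threshold = 40) {
  stopifnot(angular_threshold >= 0)
  eeg <- montage[montage$type == "EEG", , drop = FALSE]
  d <- montage_distances(eeg)
  nb <- lapply(seq_len(nrow(eeg)), function(i) {
    eeg$name[d[i, ] <= angular_threshold & seq_len(nrow(eeg)) != i]
  })
  names(nb) <- eeg$name
  isolated <- names(nb)[vapply(nb, length, 1L) == 0L]
  if (length(isolated) > 0 && angular_threshold > 0) {
    warning("isolated channel(s) in neighbor graph: ",
            paste(isolated, collapse = ", "))
  }
  nb
}

#' Test whether a neighbor graph is connected
#'
#' @param neighbors named list as returned by [build_neighbors()].
#' @return TRUE if every channel is reachable from every other.
#' @export
neighbors_connected <- function(neighbors) {
  chans <- names(neighbors)
  if (length(chans) <= 1) return(TRUE)
  seen <- chans[1]
  frontier <- chans[1]
  while (length(frontier) > 0) {
    nxt <- setdiff(unique(unlist(neighbors[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == length(chans)
}
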