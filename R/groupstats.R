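#' Trial-averaged condition power maps for one subject
#'
#' Averages the single-trial TFR within each condition, optionally after a
#' log transform (variance stabilization; off by default for group
#' statistics) and optionally boxcar-smoothed (3 x 3 bins = 6 Hz x 0.3 s;
#' on by default, applied to the trial-averaged maps).
#'
#' @param tfr an `eeg_tfr` with condition labels.
#' @param smooth apply [boxcar_smooth()] to the per-condition mean maps.
#' @param log log-transform single-trial power before averaging.
#' @return Named list, one channel x frequency x time array per condition,
#'   with the grid axes attached as attributes.
#' @export
condition_power <- function(tfr, smooth = TRUE, log = FALSE) {
  stopifnot(inherits(tfr, "eeg_tfr"))
  d <- dim(tfr$power)
  conds <- sort(unique(tfr$labels))  # deterministic order across subjects
  out <- lapply(conds, function(cond) {
    idx <- which(tfr$labels == cond)
    P <- tfr$power[idx, , , , drop = FALSE]
    if (log) P <- base::log(P)
    m <- array(colMeans(matrix(P, length(idx), prod(d[2:4]))), dim = d[2:4])
    if (smooth) {
      sm <- new_statmap(m, kind = "power", channels = tfr$channels,
                        freqs = tfr$freqs, times = tfr$times)
      m <- boxcar_smooth(sm)$values
    }
    m
  })
  names(out) <- conds
  attr(out, "channels") <- tfr$channels$name
  attr(out, "freqs") <- tfr$freqs
  attr(out, "times") <- tfr$times
  out
}

check_power_list <- function(power_list, conds = NULL) {
  stopifnot(length(power_list) >= 1)
  ref <- power_list[[1]]
  for (p in power_list) {
    if (is.null(conds)) conds <- names(p)
    if (!all(conds %in% names(p))) {
      stop("every subject must have all conditions: missing ",
           paste(setdiff(conds, names(p)), collapse = ", "))
    }
    if (!identical(attr(p, "freqs"), attr(ref, "freqs")) ||
        !identical(attr(p, "times"), attr(ref, "times")) ||
        !identical(attr(p, "channels"), attr(ref, "channels"))) {
      stop("subjects have mismatching grids")
    }
  }
  invisible(conds)
}

#' Per-subject paired condition difference maps
#'
#' @param power_list list over subjects of [condition_power()] outputs.
#' @param cond_a,cond_b condition labels; maps are `cond_a - cond_b`.
#' @return A [subject_maps()] of differences.
#' @export
paired_diff_maps <- function(power_list, cond_a, cond_b) {
  check_power_list(power_list, c(cond_a, cond_b))
  ref <- power_list[[1]]
  maps <- do.call(rbind, lapply(power_list, function(p) {
    as.vector(p[[cond_a]] - p[[cond_b]])
  }))
  subject_maps(maps, attr(ref, "channels"), attr(ref, "freqs"),
               attr(ref, "times"), kind = "diff")
}

one_sample_t_of_maps <- function(maps) {
  X <- maps$maps
  n <- nrow(X)
  m <- colMeans(X)
  v <- (colSums(X^2) - n * m^2) / (n - 1)
  tt <- m / sqrt(v / n)
  tt[v <= .Machine$double.eps * 100] <- NA_real_
  new_statmap(array(tt, dim = c(length(maps$channels), length(maps$freqs),
                                length(maps$times))),
              kind = "t", df = n - 1,
              channels = data.frame(name = maps$channels, type = "EEG",
                                    stringsAsFactors = FALSE),
              freqs = maps$freqs, times = maps$times)
}

#' Mass-univariate paired t-test between two conditions
#'
#' Dependent-samples t across subjects of (power in `cond_a` − power in
#' `cond_b`) at every channel x frequency x time bin, df = n_subjects − 1.
#'
#' @inheritParams paired_diff_maps
#' @return An `eeg_statmap` of t values. `cond_a = cond_b` gives t = 0
#'   everywhere (bins flagged NA where the difference variance is zero are
#'   set to 0 only by convention of the permutation engine, not here).
#' @export
mass_paired_t <- function(power_list, cond_a, cond_b) {
  if (length(power_list) < 2) stop("need at least 2 subjects")
  maps <- paired_diff_maps(power_list, cond_a, cond_b)
  if (cond_a == cond_b) {
    maps$maps[] <- 0
    sm <- one_sample_t_of_maps(maps)
    sm$values[] <- 0
    return(sm)
  }
  one_sample_t_of_maps(maps)
}

#' First-level (within-subject) rating regression
#'
#' For each subject and grid bin, the ordinary least-squares slope of the
#' condition-mean power on that subject's session-averaged pleasantness
#' ratings across the conditions. Subjects with zero rating variance are
#' excluded with a warning (a slope needs at least two distinct ratings).
#'
#' @param power_list list over subjects of [condition_power()] outputs; the
#'   list names must match `ratings$subject`.
#' @param ratings a `ratings_table` covering those subjects.
#' @return A [subject_maps()] of per-subject slopes (µV² per rating unit).
#' @export
first_level_regression <- function(power_list, ratings) {
  conds <- check_power_list(power_list)
  if (length(conds) < 3) {
    stop("need at least 3 conditions for a within-subject regression")
  }
  rmat <- mean_ratings(ratings)
  subjects <- names(power_list)
  stopifnot(!is.null(subjects), all(subjects %in% rownames(rmat)))
  ref <- power_list[[1]]
  nb <- length(ref[[1]])
  rows <- list()
  for (s in subjects) {
    x <- rmat[s, conds]
    dx <- x - mean(x)
    if (sum(dx^2) < .Machine$double.eps * 100) {
      warning("subject ", s, " has zero rating variance: excluded")
      next
    }
    Y <- do.call(rbind, lapply(conds, function(cond) {
      as.vector(power_list[[s]][[cond]])
    }))
    rows[[s]] <- colSums(dx * Y) / sum(dx^2)
  }
  if (length(rows) == 0) stop("no subject with rating variance")
  subject_maps(do.call(rbind, rows), attr(ref, "channels"),
               attr(ref, "freqs"), attr(ref, "times"), kind = "slope")
}

#' Second-level one-sample t-test on regression slopes
#'
#' Tests the per-subject first-level slopes against 0 at every bin,
#' df = n_subjects − 1. Bins with fewer than 2 finite slopes or zero slope
#' variance are NA.
#'
#' @param slopes a [subject_maps()] of slopes ([first_level_regression()]).
#' @return An `eeg_statmap` of one-sample t values.
#' @export
second_level_ttest <- function(slopes) {
  stopifnot(inherits(slopes, "subject_maps"))
  if (nrow(slopes$maps) < 2) stop("need at least 2 subjects")
  one_sample_t_of_maps(slopes)
}

#' Pooled within-subject (demeaned) correlation
#'
#' Pearson correlation between a per-subject-and-condition power feature
#' and the ratings after subtracting each subject's own mean (across
#' conditions) from both — eliminating non-condition-specific
#' inter-individual differences so the correlation reflects the
#' differential expression across conditions. The p-value is the ordinary
#' (uncorrected) correlation test on the pooled demeaned pairs.
#'
#' @param power_feature numeric subject x condition matrix of the scalar
#'   feature (e.g. band power in the cluster).
#' @param ratings numeric subject x condition matrix of ratings, or a
#'   `ratings_table` (session-averaged automatically).
#' @return List with `r`, `p`, `df`, `n` (pooled pairs). Zero pooled
#'   variance yields a missing `r` with a warning.
#' @export
demeaned_correlation <- function(power_feature, ratings) {
  if (inherits(ratings, "ratings_table")) ratings <- mean_ratings(ratings)
  stopifnot(is.matrix(power_feature), is.matrix(ratings),
            all(dim(power_feature) == dim(ratings)),
            ncol(power_feature) >= 2)
  # align subjects and conditions by name whenever both sides carry them
  if (!is.null(dimnames(power_feature)) && !is.null(dimnames(ratings)) &&
      setequal(colnames(power_feature), colnames(ratings)) &&
      setequal(rownames(power_feature), rownames(ratings))) {
    ratings <- ratings[rownames(power_feature), colnames(power_feature),
                       drop = FALSE]
  }
  x <- power_feature - rowMeans(power_feature)
  y <- ratings - rowMeans(ratings)
  xv <- as.vector(x); yv <- as.vector(y)
  if (stats::sd(xv) < .Machine$double.eps * 100 ||
      stats::sd(yv) < .Machine$double.eps * 100) {
    warning("zero pooled variance: correlation undefined")
    return(list(r = NA_real_, p = NA_real_, df = NA_real_,
                n = length(xv)))
  }
  ct <- stats::cor.test(xv, yv)
  list(r = unname(ct$estimate), p = ct$p.value,
       df = unname(ct$parameter), n = length(xv))
}

#' Scalar band-power feature per subject and condition
#'
#' Averages each subject's condition power maps over a channel x band x
#' window selection — the input to [demeaned_correlation()].
#'
#' @param power_list list over subjects of [condition_power()] outputs.
#' @param channels,band,window feature selection (closed intervals on the
#'   grid).
#' @return Numeric subject x condition matrix.
#' @export
condition_feature <- function(power_list, channels, band, window) {
  conds <- check_power_list(power_list)
  ref <- power_list[[1]]
  ci <- match(channels, attr(ref, "channels"))
  stopifnot(!anyNA(ci))
  fi <- grid_bins(attr(ref, "freqs"), band)
  ti <- grid_bins(attr(ref, "times"), window)
  if (length(fi) == 0 || length(ti) == 0) stop("empty bin selection")
  out <- t(vapply(power_list, function(p) {
    vapply(conds, function(cond) mean(p[[cond]][ci, fi, ti]), numeric(1))
  }, numeric(length(conds))))
  dimnames(out) <- list(names(power_list), conds)
  out
}
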