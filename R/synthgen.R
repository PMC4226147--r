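#' Pink (1/f) noise series
#'
#' Spectrally shaped white noise: independent Gaussian Fourier coefficients
#' with amplitude proportional to `1/sqrt(max(f, 1))` (flat below 1 Hz so
#' the variance stays finite), inverse-transformed and scaled to unit sample
#' standard deviation per series.
#'
#' @param n samples per series.
#' @param fs sampling rate, Hz.
#' @param m number of independent series.
#' @return `n x m` matrix, each column one unit-sd pink-noise series.
#' @export
pink_noise <- function(n, fs, m = 1) {
  stopifnot(n > 3, m >= 1)
  nf <- floor((n - 1) / 2)              # strictly positive frequencies
  f <- (1:nf) * fs / n
  g <- 1 / sqrt(pmax(f, 1))
  spec <- matrix(0+0i, n, m)
  re <- matrix(stats::rnorm(nf * m), nf, m) * g
  im <- matrix(stats::rnorm(nf * m), nf, m) * g
  spec[2:(nf + 1), ] <- complex(real = re, imaginary = im)
  spec[n:(n - nf + 1), ] <- Conj(spec[2:(nf + 1), ])
  if (n %% 2 == 0) {                    # real Nyquist coefficient
    spec[n / 2 + 1, ] <- stats::rnorm(m) / sqrt(fs / 2)
  }
  x <- Re(stats::mvfft(spec, inverse = TRUE)) / n
  sds <- sqrt(pmax(colMeans(x^2) - colMeans(x)^2, .Machine$double.eps))
  sweep(x, 2, sds, "/")
}

# raised-cosine gate: 0 outside [w1, w2], 1 inside, 0.1 s cosine ramps
ramp_gate <- function(times, window, ramp = 0.1) {
  g <- numeric(length(times))
  inside <- times >= window[1] & times <= window[2]
  g[inside] <- 1
  up <- times >= window[1] & times < pmin(window[1] + ramp, window[2])
  g[up] <- 0.5 * (1 - cos(pi * (times[up] - window[1]) / ramp))
  dn <- times > pmax(window[2] - ramp, window[1]) & times <= window[2]
  g[dn] <- pmin(g[dn], 0.5 * (1 - cos(pi * (window[2] - times[dn]) / ramp)))
  g
}

#' In-window amplitude envelope of a planted effect
#'
#' For `"hann"` a Hann taper over the effect window, for `"rect"` a
#' rectangular gate; zero outside the window. Exposed so that tests and
#' power calculations can reconstruct the planted waveform analytically:
#' a burst of amplitude A has expected in-window variance
#' `A^2 * mean(env^2) / 2` (expectation over the uniform random phase).
#'
#' @param effect an [effect_spec()].
#' @param times sample time axis, seconds.
#' @return Numeric envelope, same length as `times`.
#' @export
effect_envelope <- function(effect, times) {
  w <- effect$window
  env <- numeric(length(times))
  inside <- times >= w[1] & times <= w[2]
  if (effect$envelope == "rect") {
    env[inside] <- 1
  } else {
    u <- (times[inside] - w[1]) / (w[2] - w[1])
    env[inside] <- 0.5 * (1 - cos(2 * pi * u))
  }
  env
}

blink_weights <- function(channel_names) {
  w <- stats::setNames(numeric(length(channel_names)), channel_names)
  frontal <- c(EOG = 1, Fp1 = 0.45, Fp2 = 0.45, F7 = 0.2, F8 = 0.2,
               F3 = 0.18, F4 = 0.18, Fz = 0.15,
               FC1 = 0.06, FC2 = 0.06, FC5 = 0.05, FC6 = 0.05)
  hit <- intersect(names(frontal), channel_names)
  w[hit] <- frontal[hit]
  w
}

#' Generate one subject's synthetic epoched EEG
#'
#' Background: per-channel pink noise plus a shared pink-noise component
#' (`noise$shared_fraction` of the variance) creating realistic channel
#' correlation. Each [effect_spec()] adds a band-limited oscillation with a
#' random phase per trial; its in-window amplitude is
#' `base_amplitude * (condition_gain[c] + jitter_sc) + rating_slope *
#' rating(c)` where `rating(c)` is the subject's session-averaged rating of
#' the presented condition and `jitter_sc` is a per-subject-and-condition
#' Gaussian deviate (sd `gain_jitter_sd`, drawn once per condition).
#' Suppression-type effects (`mode = "erd"`) express the change as a
#' multiplicative amplitude gain on an ongoing oscillation, so power can
#' only be scaled, never driven negative. Ocular blinks (low-frequency Hann
#' pulses, dominant on EOG and frontal channels) and rare large
#' single-channel electronic artifacts are injected at configurable Poisson
#' rates; their ground truth is returned in `$artifacts`.
#'
#' Trials follow the blocked design: each condition appears in
#' `blocks_per_condition` blocks of `trials_per_block` consecutive trials,
#' block order randomized.
#'
#' @param config a [study_config()].
#' @param ratings this subject's slice of the ratings table (or a full
#'   table; it is subset by `subject`).
#' @param effects list of [effect_spec()] objects.
#' @param noise a [noise_spec()].
#' @param seed integer seed; output is reproducible given
#'   `(config, ratings, effects, noise, seed)`.
#' @param subject subject identifier; must match `ratings$subject`.
#' @return An `eeg_epochs` with ground-truth `$artifacts` log
#'   (`trial`, `type`, `channel`, `time`, `amplitude`).
#' @export
generate_subject_epochs <- function(config, ratings,
                                    effects = default_effects(config$conditions),
                                    noise = noise_spec(),
                                    seed = config$seed,
                                    subject = unique(ratings$subject)[1]) {
  stopifnot(inherits(config, "study_config"))
  mont <- config$montage
  for (e in effects) {
    if (!all(e$channels %in% mont$name)) {
      stop("configuration error: effect '", e$name,
           "' uses channels absent from the montage")
    }
    if (e$window[1] < config$epoch_window[1] ||
        e$window[2] > config$epoch_window[2]) {
      stop("configuration error: effect '", e$name,
           "' window outside the epoch window")
    }
    if (!all(sort(names(e$condition_gain)) == sort(config$conditions))) {
      stop("configuration error: effect '", e$name,
           "' condition_gain must be named after the conditions")
    }
  }
  rt <- ratings[ratings$subject == subject, , drop = FALSE]
  if (nrow(rt) == 0) stop("no ratings for subject ", subject)
  rating_of <- tapply(rt$rating, rt$condition, mean)[config$conditions]

  set.seed(seed)
  # blocked trial order
  block_conds <- sample(rep(config$conditions, config$blocks_per_condition))
  labels <- rep(block_conds, each = config$trials_per_block)
  ntrial <- length(labels)
  times <- seq(config$epoch_window[1], config$epoch_window[2], by = 1 / config$fs)
  nsamp <- length(times)
  nch <- nrow(mont)
  eeg_idx <- which(mont$type == "EEG")
  data <- array(0, dim = c(ntrial, nch, nsamp))

  # background noise, generated in trial chunks to bound memory
  if (noise$sd > 0 || noise$eog_sd > 0) {
    ch_sd <- ifelse(mont$type == "EEG", noise$sd, noise$eog_sd)
    a_sh <- sqrt(noise$shared_fraction)
    a_in <- sqrt(1 - noise$shared_fraction)
    chunk <- 25L
    for (t0i in seq(1L, ntrial, by = chunk)) {
      idx <- t0i:min(t0i + chunk - 1L, ntrial)
      ind <- pink_noise(nsamp, config$fs, m = length(idx) * nch)
      sh <- pink_noise(nsamp, config$fs, m = length(idx))
      for (j in seq_along(idx)) {
        cols <- ((j - 1) * nch + 1):(j * nch)
        x <- a_in * ind[, cols] + a_sh * sh[, j]   # nsamp x nch
        data[idx[j], , ] <- t(x) * ch_sd
      }
    }
  }

  # per-subject gain jitter, one deviate per effect and condition
  jitter <- lapply(effects, function(e) {
    stats::setNames(stats::rnorm(length(config$conditions), 0, e$gain_jitter_sd),
                    config$conditions)
  })

  art <- list()
  for (k in seq_along(effects)) {
    e <- effects[[k]]
    ch <- match(e$channels, mont$name)
    env <- effect_envelope(e, times)
    gate <- ramp_gate(times, e$window)
    for (tr in seq_len(ntrial)) {
      cnd <- labels[tr]
      amp_w <- max(0, e$base_amplitude * (e$condition_gain[[cnd]] +
                                            jitter[[k]][[cnd]]) +
                     e$rating_slope * rating_of[[cnd]])
      phi <- stats::runif(1, 0, 2 * pi)
      carrier <- sin(2 * pi * e$freq * times + phi)
      sig <- if (e$mode == "burst") {
        amp_w * env * carrier
      } else {
        (e$base_amplitude + (amp_w - e$base_amplitude) * gate) * carrier
      }
      for (c in ch) data[tr, c, ] <- data[tr, c, ] + sig
    }
  }

  # ocular blinks
  if (noise$blink_rate > 0) {
    bw <- blink_weights(mont$name)
    half <- noise$blink_width / 2
    for (tr in seq_len(ntrial)) {
      nb <- stats::rpois(1, noise$blink_rate)
      for (b in seq_len(nb)) {
        ctr <- stats::runif(1, times[1], times[nsamp])
        amp <- stats::rnorm(1, noise$blink_amplitude,
                            0.1 * noise$blink_amplitude)
        inside <- abs(times - ctr) <= half
        pulse <- numeric(nsamp)
        pulse[inside] <- amp * 0.5 * (1 + cos(pi * (times[inside] - ctr) / half))
        data[tr, , ] <- data[tr, , ] + outer(bw, pulse)
        art[[length(art) + 1]] <- data.frame(
          trial = tr, type = "blink", channel = "EOG",
          time = ctr, amplitude = amp, stringsAsFactors = FALSE)
      }
    }
  }

  # large single-channel electronic / movement artifacts
  if (noise$artifact_rate > 0) {
    for (tr in seq_len(ntrial)) {
      na <- stats::rpois(1, noise$artifact_rate)
      for (a in seq_len(na)) {
        ch <- sample(eeg_idx, 1)
        ctr <- stats::runif(1, times[1] + 0.05, times[nsamp] - 0.05)
        amp <- noise$artifact_amplitude * sample(c(-1, 1), 1)
        inside <- abs(times - ctr) <= 0.025
        u <- (times[inside] - ctr) / 0.025
        data[tr, ch, inside] <- data[tr, ch, inside] +
          amp * sin(pi * u) * (1 - abs(u))
        art[[length(art) + 1]] <- data.frame(
          trial = tr, type = "electronic", channel = mont$name[ch],
          time = ctr, amplitude = amp, stringsAsFactors = FALSE)
      }
    }
  }

  artifacts <- if (length(art) > 0) {
    do.call(rbind, art)
  } else {
    data.frame(trial = integer(0), type = character(0),
               channel = character(0), time = numeric(0),
               amplitude = numeric(0), stringsAsFactors = FALSE)
  }
  new_epochs(data, fs = config$fs, t0 = config$epoch_window[1],
             channels = mont[, c("name", "type")], labels = labels,
             subject = subject, artifacts = artifacts)
}

#' Generate a full synthetic study
#'
#' Ratings plus one epochs object per subject, each subject seeded
#' deterministically from the master seed.
#'
#' @inheritParams generate_subject_epochs
#' @param seed master seed; per-subject seeds are derived from it.
#' @param group_means,subject_sd,session_sd forwarded to
#'   [generate_ratings()].
#' @return List with `ratings` and `epochs` (list of `eeg_epochs`, one per
#'   subject).
#' @export
generate_study <- function(config,
                           effects = default_effects(config$conditions),
                           noise = noise_spec(),
                           seed = config$seed,
                           group_means = c(2.5, 5.5, 6.5, 7.0),
                           subject_sd = 2.2, session_sd = 1.0) {
  ratings <- generate_ratings(config, group_means = group_means,
                              subject_sd = subject_sd,
                              session_sd = session_sd,
                              seed = derive_seed(seed, 0))
  subjects <- unique(ratings$subject)
  epochs <- lapply(seq_along(subjects), function(i) {
    generate_subject_epochs(config, ratings, effects = effects,
                            noise = noise, seed = derive_seed(seed, i),
                            subject = subjects[i])
  })
  names(epochs) <- subjects
  list(ratings = ratings, epochs = epochs)
}
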