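two_ch <- data.frame(name = c("C3", "EOG"), type = c("EEG", "EOG"))

sine_epochs <- function(freq, amp = 3, fs = 250, ntrial = 1, phase = 0.7) {
  tt <- seq(-1, 2, by = 1 / fs)
  data <- array(0, dim = c(ntrial, 2, length(tt)))
  for (tr in seq_len(ntrial)) {
    data[tr, 1, ] <- amp * sin(2 * pi * freq * tt + phase + tr)
  }
  new_epochs(data, fs, -1, two_ch, labels = rep("F1", ntrial))
}

test_that("the analysis grid is 2-48 Hz in 24 bins with 0.1 s time steps", {
  tfr <- tfr_hanning(sine_epochs(20))
  expect_equal(tfr$freqs, seq(2, 48, by = 2))
  expect_length(tfr$freqs, 24)
  expect_equal(diff(tfr$times), rep(0.1, length(tfr$times) - 1),
               tolerance = 1e-9)
  expect_equal(min(tfr$times), -0.8)   # first full 0.4 s window
  expect_equal(max(tfr$times), 1.8)
  expect_false("EOG" %in% tfr$channels$name)
})

test_that("all-zero input gives all-zero power", {
  ep <- sine_epochs(20, amp = 0)
  expect_true(all(tfr_hanning(ep)$power == 0))
})

test_that("a pure 20 Hz sinusoid matches a one-shot windowed DFT oracle", {
  fs <- 250
  ep <- sine_epochs(20, amp = 3, fs = fs)
  tfr <- tfr_hanning(ep)
  ti <- which(abs(tfr$times - 0.5) < 1e-9)
  fi <- which(tfr$freqs == 20)
  # independent oracle: direct Hann-tapered DFT at the window around 0.5 s
  tt <- seq(-1, 2, by = 1 / fs)
  ci <- which(abs(tt - 0.5) < 1e-9)
  nwin <- round(0.4 * fs) + 1
  half <- (nwin - 1) / 2
  x <- ep$data[1, 1, (ci - half):(ci + half)]
  h <- 0.5 * (1 - cos(2 * pi * (0:(nwin - 1)) / (nwin - 1)))
  X <- sum(h * x * exp(-2i * pi * 20 * ((-half:half) / fs)))
  oracle <- 2 * Mod(X)^2 / sum(h)^2
  expect_lt(abs(tfr$power[1, 1, fi, ti] - oracle) / oracle, 1e-10)
  # the 20 Hz bin dominates every other bin, and equals A^2/2
  expect_equal(which.max(tfr$power[1, 1, , ti]), fi)
  expect_equal(tfr$power[1, 1, fi, ti], 3^2 / 2, tolerance = 1e-6)
})

test_that("frequencies beyond Nyquist are a configuration error", {
  ep <- sine_epochs(10, fs = 80)   # Nyquist 40 Hz < 48 Hz
  expect_error(tfr_hanning(ep), "Nyquist")
})

test_that("ERS/ERD t-map is centred on zero under the null", {
  set.seed(42)
  fs <- 250
  tt <- seq(-1, 2, by = 1 / fs)
  nch <- 8
  chans <- data.frame(name = paste0("ch", 1:nch), type = "EEG")
  data <- array(rnorm(60 * nch * length(tt)), dim = c(60, nch, length(tt)))
  ep <- new_epochs(data, fs, -1, chans, labels = rep("F1", 60))
  sm <- ers_erd_tmap(tfr_hanning(ep))
  expect_equal(sm$kind, "t")
  expect_equal(sm$df, 59)
  expect_lt(abs(mean(sm$values, na.rm = TRUE)), 0.05)
})

test_that("planted mu suppression puts the strongest desynchronization at C3", {
  cfg <- study_config(n_subjects = 1, blocks_per_condition = 1,
                      trials_per_block = 25)
  r <- generate_ratings(cfg, seed = 2)
  eff <- effect_spec("mu", channels = "C3", band = c(10, 14), freq = 12,
                     window = c(0.2, 1.6), base_amplitude = 8,
                     condition_gain = stats::setNames(rep(sqrt(0.5), 4),
                                                      cfg$conditions),
                     mode = "erd")
  ep <- generate_subject_epochs(cfg, r, effects = list(eff),
                                noise = noise_spec(sd = 2, blink_rate = 0,
                                                   artifact_rate = 0),
                                seed = 13, subject = "S01")
  sm <- boxcar_smooth(ers_erd_tmap(tfr_hanning(ep)))
  fi <- which(sm$freqs >= 10.5 & sm$freqs <= 14.5)
  ti <- which(sm$times >= 0.3 & sm$times <= 0.6)
  sub <- sm$values[, fi, ti, drop = FALSE]
  idx <- which(sub == min(sub, na.rm = TRUE), arr.ind = TRUE)
  expect_equal(sm$channels$name[idx[1, 1]], "C3")
  expect_lt(min(sub, na.rm = TRUE), -3)
})

test_that("a single ERS/ERD bin equals the hand-coded paired-t oracle", {
  set.seed(5)
  fs <- 250
  tt <- seq(-1, 2, by = 1 / fs)
  data <- array(rnorm(20 * 2 * length(tt)), dim = c(20, 2, length(tt)))
  ep <- new_epochs(data, fs, -1, two_ch, labels = rep("F1", 20))
  tfr <- tfr_hanning(ep)
  sm <- ers_erd_tmap(tfr, baseline = c(-0.4, -0.2))
  fi <- 7; ti <- 20
  bidx <- which(tfr$times >= -0.4 & tfr$times <= -0.2)
  d <- tfr$power[, 1, fi, ti] -
    rowMeans(tfr$power[, 1, fi, bidx, drop = TRUE])
  oracle <- mean(d) / (stats::sd(d) / sqrt(length(d)))
  expect_lt(abs(sm$values[1, fi, ti] - oracle), 1e-10)
  expect_equal(oracle, unname(stats::t.test(d)$statistic), tolerance = 1e-12)
})

test_that("boxcar smoothing preserves constants and spreads an impulse as 1/9", {
  vals <- array(2.5, dim = c(3, 10, 12))
  sm <- new_statmap(vals, "t", 9,
                    data.frame(name = c("A", "B", "C"), type = "EEG"),
                    freqs = seq(2, 20, 2), times = seq(0, 1.1, 0.1))
  out <- boxcar_smooth(sm)
  expect_equal(out$values, vals)
  imp <- sm
  imp$values[] <- 0
  imp$values[2, 5, 6] <- 1
  out <- boxcar_smooth(imp)
  expect_equal(out$values[2, 4:6, 5:7], array(1 / 9, dim = c(3, 3)),
               ignore_attr = TRUE)
  expect_equal(sum(out$values[2, , ]), 1)      # interior mass conserved
  expect_equal(sum(out$values[c(1, 3), , ]), 0) # no spatial smoothing
  expect_error(boxcar_smooth(imp, n_freq_bins = 21), "kernel larger")
})

test_that("band and window selection uses closed intervals on bin centers", {
  # craft a TFR whose power equals its frequency bin center
  freqs <- seq(2, 48, 2)
  times <- seq(-0.8, 1.8, 0.1)
  power <- array(0, dim = c(4, 1, 24, length(times)))
  for (f in 1:24) power[, , f, ] <- freqs[f]
  tfr <- structure(list(power = power, freqs = freqs, times = times,
                        channels = data.frame(name = "C3", type = "EEG"),
                        labels = rep("F1", 4), subject = "S",
                        window_length = 0.4, fs = 250),
                   class = "eeg_tfr")
  expect_equal(unname(band_power(tfr, c(26, 30), c(0, 1))[, 1]),
               rep(28, 4))              # bins {26, 28, 30}
  expect_equal(unname(band_power(tfr, c(10.5, 14.5), c(0, 1))[, 1]),
               rep(13, 4))              # bins {12, 14}
  expect_equal(unname(band_power(tfr, c(14.5, 17.5), c(0, 1))[, 1]),
               rep(16, 4))              # bin {16}
  expect_error(band_power(tfr, c(49, 60), c(0, 1)), "empty bin")
  expect_error(band_power(tfr, c(26, 30), c(5, 6)), "empty bin")
})

test_that("band power scales quadratically with planted amplitude", {
  p1 <- tfr_hanning(sine_epochs(28, amp = 2, ntrial = 4))
  p2 <- tfr_hanning(sine_epochs(28, amp = 4, ntrial = 4))
  b1 <- band_power(p1, c(26, 30), c(0, 1), pool_channels = TRUE)
  b2 <- band_power(p2, c(26, 30), c(0, 1), pool_channels = TRUE)
  expect_equal(mean(b2) / mean(b1), 4, tolerance = 0.01)
})
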