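mini_cfg <- study_config(n_subjects = 2, blocks_per_condition = 1,
                         trials_per_block = 6, montage = mini_montage())
mini_ratings <- generate_ratings(mini_cfg, seed = 3)
silent <- noise_spec(sd = 0, eog_sd = 0, blink_rate = 0, artifact_rate = 0)

test_that("no effects and zero noise give all-zero data", {
  ep <- generate_subject_epochs(mini_cfg, mini_ratings, effects = list(),
                                noise = silent, seed = 1, subject = "S01")
  expect_true(all(ep$data == 0))
  expect_equal(dim(ep$data), c(24, nrow(mini_cfg$montage), 751))
})

test_that("generation is reproducible given the seed", {
  eff <- default_effects(mini_cfg$conditions)["mu"]  # C3 is in the montage
  e1 <- generate_subject_epochs(mini_cfg, mini_ratings, effects = eff,
                                seed = 9, subject = "S01")
  e2 <- generate_subject_epochs(mini_cfg, mini_ratings, effects = eff,
                                seed = 9, subject = "S01")
  expect_identical(e1$data, e2$data)
  expect_identical(e1$labels, e2$labels)
})

test_that("planted burst energy matches the analytic variance within 1%", {
  eff <- effect_spec("test_burst", channels = "Cz", band = c(26, 30),
                     freq = 28, window = c(0.35, 0.65),
                     base_amplitude = 3,
                     condition_gain = stats::setNames(c(1, 1, 1, 1),
                                                      mini_cfg$conditions),
                     rating_slope = 0.5, mode = "burst", envelope = "hann")
  ep <- generate_subject_epochs(mini_cfg, mini_ratings,
                                effects = list(eff), noise = silent,
                                seed = 4, subject = "S01")
  tt <- epoch_times(ep)
  win <- tt >= 0.35 & tt <= 0.65
  env <- effect_envelope(eff, tt)
  rmat <- mean_ratings(mini_ratings)
  cz <- which(ep$channels$name == "Cz")
  for (cond in mini_cfg$conditions) {
    A <- 3 + 0.5 * rmat["S01", cond]
    analytic <- A^2 * mean(env[win]^2) / 2
    trials <- which(ep$labels == cond)
    observed <- mean(ep$data[trials, cz, win]^2)
    expect_equal(observed, analytic, tolerance = 0.01)
  }
})

test_that("a planted 28 Hz burst peaks in the 26-30 Hz periodogram range", {
  eff <- effect_spec("b", channels = "Cz", band = c(26, 30), freq = 28,
                     window = c(0.2, 0.8), base_amplitude = 4,
                     condition_gain = stats::setNames(rep(1, 4),
                                                      mini_cfg$conditions),
                     mode = "burst")
  ep <- generate_subject_epochs(mini_cfg, mini_ratings,
                                effects = list(eff), noise = silent,
                                seed = 5, subject = "S01")
  tt <- epoch_times(ep)
  win <- which(tt >= 0.2 & tt <= 0.8)
  cz <- which(ep$channels$name == "Cz")
  x <- ep$data[, cz, win]
  freqs <- seq(2, 48, by = 2)
  pw <- vapply(freqs, function(f) oracle_band_power(x, ep$fs, f), numeric(1))
  expect_true(freqs[which.max(pw)] %in% c(26, 28, 30))
})

test_that("rating-linked beta power rises monotonically with the rating", {
  ratings <- data.frame(subject = "S01", session = "pre",
                        condition = mini_cfg$conditions,
                        rating = c(2L, 4L, 6L, 8L))
  class(ratings) <- c("ratings_table", "data.frame")
  eff <- effect_spec("beta", channels = "Cz", band = c(26, 30), freq = 28,
                     window = c(0.35, 0.65), base_amplitude = 1,
                     condition_gain = stats::setNames(rep(1, 4),
                                                      mini_cfg$conditions),
                     rating_slope = 0.8, mode = "burst")
  ep <- generate_subject_epochs(mini_cfg, ratings, effects = list(eff),
                                noise = noise_spec(sd = 1, blink_rate = 0,
                                                   artifact_rate = 0),
                                seed = 6, subject = "S01")
  tt <- epoch_times(ep)
  win <- which(tt >= 0.35 & tt <= 0.65)
  cz <- which(ep$channels$name == "Cz")
  bp <- vapply(mini_cfg$conditions, function(cond) {
    x <- ep$data[ep$labels == cond, cz, win, drop = TRUE]
    mean(vapply(c(26, 28, 30), function(f)
      oracle_band_power(x, ep$fs, f), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(bp) > 0))
})

test_that("deepest mu condition gain yields the lowest C3 stimulation power", {
  gains <- stats::setNames(c(0.3, 0.7, 0.7, 0.7), mini_cfg$conditions)
  eff <- effect_spec("mu", channels = "C3", band = c(10, 14), freq = 12,
                     window = c(0.3, 1.5), base_amplitude = 8,
                     condition_gain = gains, mode = "erd")
  ep <- generate_subject_epochs(mini_cfg, mini_ratings,
                                effects = list(eff),
                                noise = noise_spec(sd = 1, blink_rate = 0,
                                                   artifact_rate = 0),
                                seed = 7, subject = "S01")
  tt <- epoch_times(ep)
  win <- which(tt >= 0.5 & tt <= 1.3)
  c3 <- which(ep$channels$name == "C3")
  bp <- vapply(c("F1", "F4"), function(cond) {
    x <- ep$data[ep$labels == cond, c3, win, drop = TRUE]
    mean(vapply(c(12, 14), function(f)
      oracle_band_power(x, ep$fs, f), numeric(1)))
  }, numeric(1))
  expect_lt(bp[["F1"]], bp[["F4"]])
})

test_that("effects referencing unknown channels or bad bands are rejected", {
  eff <- effect_spec("x", channels = "XX9", band = c(26, 30),
                     window = c(0, 1), base_amplitude = 1,
                     condition_gain = stats::setNames(rep(1, 4),
                                                      mini_cfg$conditions))
  expect_error(generate_subject_epochs(mini_cfg, mini_ratings,
                                       effects = list(eff), seed = 1,
                                       subject = "S01"),
               "absent from the montage")
  expect_error(effect_spec("y", "C3", band = c(40, 60), window = c(0, 1),
                           base_amplitude = 1, condition_gain = 1),
               "within \\[2, 48\\]")
})

test_that("default design produces 50 trials per condition in blocked order", {
  cfg <- study_config()
  r <- generate_ratings(cfg, seed = 2)
  ep <- generate_subject_epochs(cfg, r, seed = 2, subject = "S01")
  expect_equal(unname(table(ep$labels)[cfg$conditions]),
               rep(50L, 4), ignore_attr = TRUE)
  # blocked: labels change only at block boundaries (8 blocks of 25)
  expect_lte(sum(diff(as.integer(factor(ep$labels))) != 0), 7L)
  expect_true(all(table(ep$labels[1:25]) %in% c(0L, 25L)))
  expect_equal(dim(ep$data), c(200, 32, 751))
})
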