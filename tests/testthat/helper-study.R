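# Shared fixtures, built in code and cached across test files.

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache, inherits = FALSE)
}

# One fully processed default synthetic study (13 subjects): cleaned epochs
# -> TFR -> smoothed condition power maps + decoding feature sets.
processed_study <- function(seed) {
  cache_get(paste0("study_", seed), function() {
    cfg <- study_config()
    study <- generate_study(cfg, seed = seed)
    power <- list(); beta <- list(); mu <- list()
    for (s in names(study$epochs)) {
      r1 <- reject_by_amplitude(study$epochs[[s]])
      oc <- remove_ocular_components(r1$epochs)
      tfr <- tfr_hanning(oc$epochs)
      power[[s]] <- condition_power(tfr)
      beta[[s]] <- extract_features(tfr, list(band = c(26, 30),
                                              window = c(0.35, 0.65)))
      mu[[s]] <- extract_features(tfr, list(band = c(10.5, 14.5),
                                            window = c(0.3, 0.6)))
    }
    list(config = cfg, ratings = study$ratings, power = power,
         beta = beta, mu = mu)
  })
}

# 13 subjects whose band-power features carry no label information:
# all planted effects identical across conditions and unlinked to ratings.
null_feature_study <- function(seed) {
  cache_get(paste0("null_", seed), function() {
    cfg <- study_config()
    eff <- default_effects(cfg$conditions)
    eff$mu_high$condition_gain[] <- 0.6
    eff$beta$rating_slope <- 0
    ratings <- generate_ratings(cfg, seed = seed)
    subjects <- unique(ratings$subject)
    beta <- list()
    for (i in seq_along(subjects)) {
      ep <- generate_subject_epochs(cfg, ratings, effects = eff,
                                    seed = seed * 1000L + i,
                                    subject = subjects[i])
      tfr <- tfr_hanning(ep)
      beta[[subjects[i]]] <- extract_features(
        tfr, list(band = c(26, 30), window = c(0.35, 0.65)))
    }
    list(config = cfg, ratings = ratings, beta = beta)
  })
}

# small montage for fast generator tests
mini_montage <- function(chans = c("C3", "Cz", "Oz", "Fp1", "Fp2", "EOG")) {
  m <- montage_1020()
  m[m$name %in% chans, , drop = FALSE]
}

# independent windowed-periodogram oracle: mean power of `x[trials, samples]`
# at frequency f over the sample window, Hann-tapered direct DFT
oracle_band_power <- function(x, fs, f) {
  n <- ncol(x)
  h <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
  tau <- (0:(n - 1)) / fs
  e <- exp(-2i * pi * f * tau)
  co <- as.vector(x %*% (h * e)) / sum(h)
  mean(2 * Mod(co)^2)
}
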