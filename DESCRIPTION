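Package: affectEEG
Title: Time-Frequency Statistics and Single-Trial Decoding for Affective Tactile EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for event-related oscillatory EEG studies of
    affective touch: Hanning-taper time-frequency decomposition on a fixed
    2-48 Hz grid, baseline-referenced ERS/ERD t-maps, cluster-based
    sign-flip permutation statistics over channel x frequency x time for
    paired contrasts and two-level rating regressions, single-trial
    decoding of stimulus condition from band-power features with a
    ridge-regularized (MAP Bayesian) logistic classifier under stratified
    cross-validation, and behavioral statistics (intraclass correlation,
    repeated-measures ANOVA, paired contrasts). Ships a synthetic-data
    generator that emulates a 13-subject, 4-condition, 50-trials-per-
    condition tactile stimulation study on a 32-channel 10-20 montage with
    pink-noise background, ocular artifacts, a condition-linked mu-band
    suppression at C3 and a rating-linked beta-band response over right
    temporo-parietal channels, so the whole pipeline is testable end to end
    without any recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
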