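---
title: "Dissociating sensory and affective tactile EEG responses: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissociating sensory and affective tactile EEG responses: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affectEEG)
```

## The scientific problem

When the skin is caressed with materials of different texture, the EEG
carries two kinds of information that are easy to conflate: the *sensory*
response to the physical stimulation itself, and an *affective* response
that tracks how pleasant the stimulation feels to the individual.
`affectEEG` implements an analysis chain designed to pull these apart in a
blocked tactile-stimulation design: 13 subjects, four fabric conditions
(F1..F4) presented in two blocks of 25 two-second caresses each, 32-channel
10-20 EEG, and 9-point pleasantness ratings collected before and after the
recording.

Two oscillatory signatures anchor the dissociation:

* **mu suppression** (~10-20 Hz over contralateral sensorimotor cortex,
  electrode C3): the dominant response to tactile stimulation per se. Its
  condition differences follow the physical texture of the stimuli, not
  their subjective valence.
* **a beta-band response** (26-30 Hz over right temporo-parietal
  electrodes, ~0.35-0.65 s after onset) whose amplitude scales with each
  subject's own pleasantness rating of the presented fabric — the
  affective correlate.

The pipeline quantifies both with the same machinery: Hanning-taper
time-frequency analysis, baseline-referenced ERS/ERD t-maps, mass-univariate
group statistics corrected by cluster-based sign-flip permutation, pooled
within-subject correlations, and single-trial decoding from band-power
features.

## Analysis model

### Time-frequency decomposition

`tfr_hanning()` computes sliding-window Fourier power with a 0.4 s Hann
taper at frequencies 2-48 Hz in 2 Hz steps (24 bins) and window centers
every 0.1 s. Power is normalized as
$P(f, t) = 2\,|{\textstyle\sum_n} h_n x_n e^{-i2\pi f n/f_s}|^2 / (\sum_n h_n)^2$,
so a pure sinusoid of amplitude $A$ at a grid frequency yields $A^2/2$ —
its variance. Any constant normalization would do, because every downstream
statistic is a contrast or ratio; this one is fixed and documented. With a
0.4 s taper the spectral mainlobe is roughly ±5 Hz wide, which matters when
interpreting band features: activity at 16-18 Hz bleeds measurably into the
14 Hz bin.

Power spectra and t-spectra are smoothed with a separable 3 × 3 bin boxcar
(0.3 s × 6 Hz) to absorb inter-individual variation in spectral peaks;
truncated kernels at the grid edges are renormalized so constants are
preserved and power stays non-negative. Band labels that do not fall on the
2 Hz grid (10.5-14.5, 14.5-17.5 Hz) select the bins whose centers lie
inside the closed interval — {12, 14} and {16} respectively.

### ERS/ERD statistics

`ers_erd_tmap()` computes, per channel × frequency × time bin, the
dependent-samples t across trials of bin power minus that trial's mean
baseline power (baseline −0.4 to −0.2 s), df = n−1. Negative t is
desynchronization. Zero-variance bins are flagged `NA` and excluded from
cluster maxima.

### Cluster-based permutation inference

Mass-univariate group tests (paired condition contrast via
`mass_paired_t()`, or a two-level rating regression via
`first_level_regression()` + `second_level_ttest()`) are corrected over the
whole channel × frequency × time grid by `cluster_permutation_test()`:

1. a group one-sample t at every bin of the subject-level maps;
2. bins with |t| above the two-tailed critical value at `cluster_alpha`
   (default 0.05, df = n−1) are clustered under rook adjacency in frequency
   and time plus montage adjacency in space (great-circle neighbor graph,
   default threshold 40°), separately per sign;
3. each cluster is scored by its mass (sum of t);
4. the null distribution of the maximum |mass| is built from random
   sign-flips of the subject maps — exchangeable under the paired/one-sample
   null — and corrected p-values are `(1 + #{null ≥ mass}) / (1 + n_perm)`.

When `2^n_subjects ≤ n_perm` the sign patterns are enumerated exhaustively
and p-values are exact tail proportions. The cluster-forming threshold,
permutation count (default 1000; 500 in the bundled study runs) and alpha
are exposed as configuration with documented defaults; none of them is a
canonical constant of the method.

The within-subject *demeaned correlation* (`demeaned_correlation()`)
subtracts each subject's mean across conditions from both the scalar power
feature and the ratings before pooling, removing non-condition-specific
inter-individual differences. Its p-value is the ordinary uncorrected
correlation test on the pooled pairs, as is conventional for this display;
note that demeaning leaves ~3 free pairs per subject (39 effective, not
52), so the test is mildly anticonservative and single draws of a null
study scatter by roughly ±0.15 in r.

### Single-trial decoding

`fit_bayes_logistic()` is a MAP Bayesian logistic classifier: logistic
regression with a zero-mean isotropic Gaussian prior of precision λ
(default 1) on the weights, intercept unpenalized, fitted by Newton/IRLS to
a gradient-norm tolerance of 1e-8. The prior guarantees finite weights on
separable data; a Laplace-approximate moderated prediction is available
behind a flag. Classifiers in this family are sometimes equipped with
structured spatio-temporal priors; with a small channel-vector feature set
an isotropic Gaussian (ridge) prior is a faithful surrogate, and we
document this as a deliberate simplification.

`crossval_accuracy()` and `one_vs_rest_accuracy()` run stratified fivefold
cross-validation. Features (band- and window-averaged log power per channel
— the log stabilizes the heavy right tail of power) are standardized with
training-fold statistics only; one-vs-rest predictions take the argmax of
the predictive probabilities with ties broken towards the first class
level. Decoding is always per subject (models are never pooled), and group
summaries average the per-subject fold means; both the fold-mean-then-
subject-mean and trial-pooled conventions are recoverable from the returned
`cv_result` objects.

### Behavioral statistics

`icc_consistency_average()` implements the two-way, average-measure ICC
from the mean-squares decomposition; "two-way mixed, average measure" is
interpreted as the consistency form ICC(3,k) = (MS_rows − MS_error)/MS_rows
(the absolute-agreement variant is available via `type = "agreement"`),
with F-distribution confidence bounds. `rm_anova()` is the one-way
repeated-measures F through `stats::aov()` with a subject error stratum
(Greenhouse–Geisser correction optional), and `paired_t()` wraps the
dependent t-test with explicit degenerate-case handling (identical inputs:
t = 0, p = 1). The contrast convention is first argument minus second.

## What the synthetic generator emulates

Because no public recordings accompany the design, the package ships a
generator that reproduces the *statistical structure* the analysis assumes,
so every stage is testable end to end.

**Ratings** (`generate_ratings()`): group means (2.5, 5.5, 6.5, 7.0) make
F1 clearly least liked with small differences among F2-F4; per-subject
preference deviations (sd 2.2) reproduce a pooled correlation of ~0.58
between the group condition ranking and individual ratings; the post
session adds small integer noise (sd 1.0), which yields session
reliabilities of ICC ≈ 0.95 by construction.

**EEG** (`generate_subject_epochs()`): pink-noise background (10 µV per
channel, 30% shared across channels), ocular blink pulses dominant on EOG
and frontal channels at a Poisson rate, rare large single-channel
artifacts, and three planted oscillatory components:

* a condition-independent 12 Hz mu rhythm at C3 (8 µV) suppressed to 60%
  amplitude during stimulation — the stimulation-per-se response;
* a condition-linked 17.5 Hz (higher mu) suppression at C3 (6 µV) with
  gains (0.45, 0.82, 0.48, 0.50) for F1..F4: deepest for F1, shallowest
  for F2, i.e. ordered by physical texture rather than valence, so the
  lower-mu feature stays essentially uncorrelated with the ratings;
* an additive 28 Hz burst (0.35-0.65 s) on five right temporo-parietal
  channels with amplitude 2 µV + 0.5 µV × the subject's own session-mean
  rating — the affective, rating-linked response.

Suppression is always expressed multiplicatively (gain < 1 on an ongoing
oscillation) so power cannot become negative; bursts have random phase per
trial and a Hann envelope. Per-subject gain jitter (sd 0.02 and 0.03 for
the two mu components) models inter-subject effect-size variability.

These choices were calibrated once to the intended operating point of the
emulated design — rating-rank correlation ≈ 0.58, a robust F1-vs-F4 mu
difference in the higher mu band with a weak (r ≈ 0.2, non-significant)
pooled mu-rating correlation, a single significant right-posterior beta
cluster, and decodable beta features — and then frozen. What the generator
does *not* emulate: volume-conduction topographies (effects live on a fixed
channel set), 1/f knee structure and line noise, non-stationary artifacts,
subject-specific spectral peaks, or any genuine neurovascular/behavioral
coupling. Passing tests therefore demonstrate the correctness and
calibration of the *analysis*, not the realism of the data.

## Numerical and design choices

* Default sampling rate 250 Hz (acquisition was at 1000 Hz; the 2 Hz ×
  0.1 s analysis grid is unaffected, and a config switch restores
  1000 Hz). Simulation sizes in tests and the acceptance script were
  chosen at desk scale: 13 subjects × 200 trials, 500 permutations per
  cluster test, 200-300 null studies for error-rate calibration.
* Epoch sample counts use inclusive endpoints (`span × fs + 1`); all time
  axes are seconds relative to stimulus onset.
* Trial rejection replaces visual inspection by a deterministic
  peak-to-peak criterion, default 200 µV on EEG channels (EOG excluded),
  applied before and after component removal. The default is set above the
  typical frontal blink excursion so ocular artifacts are handled by the
  PCA stage, mirroring the two-stage manual procedure it stands in for.
* Ocular cleaning selects principal components by |Pearson r| ≥ 0.7 with
  the EOG channel, iterating until no component reaches threshold — this
  makes the operation idempotent; null-space components are never selected.
* The cluster test auto-switches to exhaustive sign enumeration whenever
  `2^n ≤ n_perm`, making small-n results exact and reproducible without a
  seed.
* Log-transform of power is OFF for group statistics and ON for decoding
  features, both switchable. Smoothing is applied to trial-averaged
  condition maps and to t-maps; both orders (smooth before or after the
  baseline t) are supported by composing `boxcar_smooth()` where wanted.
* Ratings enter the regression as the pre/post session mean (their
  reliability justifies averaging); the rating-to-power link in the
  generator uses the same session mean.
* Ties in one-vs-rest argmax go to the lowest class index; fold assignment
  is per-class round-robin after a seeded shuffle.

## Known limitations

* The neighbor graph uses schematic 10-20 positions, not digitized
  electrode locations; neighborhoods are standard but approximate.
* The demeaned pooled correlation inherits the anticonservativeness noted
  above; at 13 subjects × 4 conditions a single synthetic study's mu
  correlation occasionally crosses nominal significance even though the
  generator plants no rating link — the dissociation tests therefore
  aggregate over replicate studies.
* `rm_anova()` implements the one-way within-subject design only, matching
  the study; there is no general factorial RM-ANOVA.
* The classifier is linear with an isotropic prior; no spatio-temporal
  prior structure, kernels, or time-resolved decoding.
* Source localization, vendor raw-file parsing and channel interpolation
  are out of scope.

## Reproducing the study-scale analysis

```{r, eval = FALSE}
cfg <- study_config()                       # 13 subjects, 4 fabrics, 250 Hz
run_pipeline(cfg, out_dir = "run", seed = 1, n_perm = 500)
pipeline_report("run")
```

The run directory then contains the ratings table, cleaning logs, cluster
results (JSON + TSV of bin memberships), demeaned correlations, per-subject
decoding accuracies and the behavioral report, plus a manifest with output
hashes: rerunning with the same config and seed reproduces every hash. The
full default pipeline completes in a few minutes on one CPU.
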