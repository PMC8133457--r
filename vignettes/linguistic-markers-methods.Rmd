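---
title: "Methods: linguistic markers of mental health in longitudinal blog cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linguistic markers of mental health in longitudinal blog cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lingmark)
```

## The scientific problem

People who blog leave a fortnight-by-fortnight record of their language.
Dictionary-based text analysis (LIWC) condenses each post into 68
percent-of-words category scores — pronouns, emotion words, hedges,
disfluencies, and so on. If some of these categories track mental state,
two distinct questions arise:

1. **Between subjects** — across people, do those who score higher on
   depression (PHQ-9), anxiety (GAD-7) or suicidal ideation (PHQ-9
   item 9) use language differently, on average?
2. **Within subjects** — for a single person followed over 36 weeks,
   do *changes* in their language track *changes* in their symptoms?

The second does not follow from the first. Relationships estimated
across people generalise to individuals over time only when the
underlying process is (approximately) ergodic; `lingmark` implements
both analyses plus a synthetic-cohort generator in which the degree of
ergodicity is an explicit knob, so the whole pipeline can be validated
against known truth.

## Data model

The long per-window table (`new_cohort()`) holds one row per
participant per fortnight: PHQ-9 total (0–27), GAD-7 total (0–21),
item 9 (0–3; any score above 0 flags suicidal ideation,
`suicidal_flag()`), a panic-attack count carried as a passthrough
field, the number of blog posts, per-post word counts, and the
window-averaged feature vector. A feature vector is missing exactly
when the window has no posts; an assessment can be missing
independently. Severity bands for both scales follow the standard cut
points (0–4 nil-minimal, 5–9 mild, 10–14 moderate, 15–19 moderately
severe, 20 and above severe).

Two derived tables drive the analyses:

* `cross_section()` averages each participant's features and symptom
  scores over windows where a feature vector and the assessment
  co-occur — only concurrent pairs are informative about the
  feature–symptom link. This is the between-subject table.
* `summarize_activity()` reproduces per-participant completion and
  posting totals with cohort means, sample SDs (n − 1) and ranges.

Window averaging of post-level scores is unweighted
(`average_window_features()`). Weighting posts by word count would be a
defensible alternative; the unweighted mean is the plain reading of
"averaged" and is what we implement.

## Between-subject screening

Every feature is correlated with every target by Spearman's rank
correlation (the Pearson correlation of midranks), a 68 × 3 = 204-test
family. Rank correlation is deliberate: several LIWC categories
(disfluencies in particular) are strongly skewed with a low base rate,
and monotone association is the defensible target of inference.

Family-wise error is controlled by the max-statistic permutation
procedure (`max_stat_permutation()`): each permutation shuffles the
symptom rows jointly across participants, recomputes all 204
correlations, and records the most extreme |rho|. The corrected
p-value of a pair is the add-one proportion
`(1 + #{max ≥ |rho_obs|}) / (n_perm + 1)`, and the (1 − alpha) quantile
of the extreme-value distribution is the family significance threshold
on the |rho| scale. Because the null distribution is that of the
*maximum*, it automatically adapts to the family size, and corrected
p-values dominate uncorrected ones. Design choices worth making
explicit:

* The two-sided family statistic is max |rho| ("most extreme positive
  or negative").
* All three targets are permuted with a *single* permutation per
  iteration, preserving their mutual correlation under the null; a
  `joint = FALSE` switch permutes targets independently for
  comparison. The difference is small in practice (both are valid
  nulls for each pair), but the joint scheme is the one that treats
  "the symptom scores" as one exchangeable block.
* Uncorrected p-values use the exact Spearman null for n ≤ 10 and the
  t approximation otherwise. Corrected permutation p-values have a
  floor of 1/(n_perm + 1); an analytic p below that floor is reported
  as-is, which is the standard finite-sample behaviour.
* Missing cells are pairwise-deleted per (feature, target) pair. After
  the final-sample filter the cross-sectional table is complete in
  features, so this matters mainly for partially missing targets.
* `exhaustive = TRUE` enumerates all n! permutations (n ≤ 8), used by
  the test suite to check the sampled procedure against exact
  enumeration.

Confidence intervals for rho are percentile bootstrap over
participants (`bootstrap_ci()`); degenerate resamples (constant
vectors) are redrawn and counted.

## PLS regression

Multivariate prediction uses partial least squares regression
(`fit_pls()`): components are directions of maximal covariance between
the z-transformed feature and target matrices, extracted by the
deterministic SIMPLS deflation scheme. At full rank the coefficients
equal the least-squares solution (tested against a normal-equations
oracle at 1e−8); with one target and one component the weight vector
is proportional to the feature–target covariance vector. Component
signs are fixed so each weight vector's largest-magnitude entry is
positive; weights, loadings and y-loadings are flipped jointly so
predictions are unchanged.

The number of components is chosen by 5-fold cross-validation
(`cv_select_ncomp()`), with MSE measured on the standardized target
scale so that zero components — the train-fold mean predictor — sits
near 1 and the reported `relative_change_vs_zero` is the percent MSE
change of the selected model. The stopping rule is the first local
minimum: the smallest m with `mse[m+1] >= mse[m]`. Standardization is
refit inside each training fold and applied to its test fold; this
avoids leakage. A `scope = "global"` variant standardizes once up
front, for fidelity comparisons with pipelines that z-transform before
cross-validating. The candidate maximum is 10 components, capped by
rank and fold size.

The restricted model keeps the `k = 4` features whose one-component
loadings are most stable across 10,000 participant bootstrap
resamples, scored by `z = mean(loading) / SD(loading)`
(`bootstrap_select_features()`). "Loading" here is the normalized
one-component weight vector; because the sign of a latent component is
arbitrary, each resample's vector is sign-aligned with the full-sample
fit before accumulating — without this, bootstrap SDs are inflated by
sign flips and the z-scores are meaningless. Ties in |z| are broken by
feature label so selection is deterministic given the seed.

`predicted_vs_observed()` reports the per-target Pearson correlation
(and its square) between model predictions and observations with a
bootstrap CI, and `fit_multitarget()` fits the three symptom targets
jointly in one model.

## Within-subject generalizability

`within_subject_analysis()` applies the group-level (restricted) model
to each participant's own time series: one prediction per window with
both features and the assessment, correlated with the observed scores
over time (Pearson; a rank variant is available via `method`). The
per-participant correlations are Fisher-z transformed (`atanh`) and the
mean z is tested against zero with a one-sample t-test, swept over
minimum-assessment thresholds 3..18, since participants complete very
different numbers of assessments.

Participants with fewer than 3 usable windows, or with zero variance in
either series, have an undefined correlation; they are *excluded and
counted*, not clamped — clamping |r| = 1 cases to a finite z would bias
the mean. A threshold leaving fewer than 2 usable participants yields
an aggregate row marked unavailable rather than an error.

## The synthetic cohort generator

`generate_cohort()` draws from an explicit generative model:

* participant trait `u ~ N(0, 1)`; per-window latent state
  `s = u + e`, `e ~ N(0, symptom_noise_sd²)` shared by both scales;
* continuous symptom scores affine in `s` (defaults anchored at PHQ-9
  mean 14.5 / SD ≈ 5.6 and GAD-7 mean 11.6 / SD ≈ 4.9, matching a
  clinically elevated blogging cohort), then rounded and clipped to
  the bounded integer scales; item 9 is a coarsened monotone function
  of the continuous depression score, so `phq9_total >= item9` holds
  by construction;
* feature j is
  `baseline_j + loading_j * (w*s + (1-w)*u) + noise`, truncated at 0
  (LIWC scores are percentages), where `w = within_coupling` is the
  ergodicity knob: at `w = 1` features track the window state (the
  within-subject relation equals the between-subject one); at `w = 0`
  the systematic part is the time-invariant trait only. Per-window
  feature measurement noise remains at `w = 0` — truly constant
  features would make every within-subject correlation undefined and
  the regime untestable;
* assessments and blog windows are deleted independently with the
  configured probabilities (defaults 0.58 and 0.5, giving ≈ 7.5 of 18
  completed assessments, the completion level of the motivating
  cohort); post and word counts are negative-binomial, since observed
  posting activity is far over-dispersed (variance ≫ mean);
* everything is driven by one seed; identical config + seed gives a
  bit-identical table. `degrade_to_study_profile()` additionally
  imposes an exact per-participant completion profile, e.g. one taken
  from a published activity table.

What the generator does *not* emulate: real LIWC score distributions
(Gaussian-with-truncation is a modelling convenience; real categories
are often zero-inflated and skewed), autocorrelated symptom
trajectories, platform-specific posting bursts, and scale-specific
measurement error (both scales share one latent state, so their
continuous scores are more tightly coupled than real PHQ-9/GAD-7
pairs). Passing tests therefore demonstrate correctness of the
*procedures* under a known truth, not distributional realism of blog
data.

Truncation at 0 attenuates planted correlations when the baseline is
small relative to the feature SD; the baseline is configurable, and
calibration checks that need the closed-form value (the
bivariate-normal Spearman identity `rho_s = (6/pi) asin(r/2)`) use a
high baseline where the attenuation is negligible.

## Numerical and validation choices

* Validation errors are classed conditions naming the offending field;
  duplicate keys, partial feature vectors and non-numeric symptom
  cells are distinct classes.
* Undefined correlations (constant vectors) are signalled as `NA` and
  propagate as missing results; they are never silently zeroed.
* Permutation p-values use the add-one convention (never exactly 0);
  exhaustive enumeration divides by n! with the identity included.
* All stochastic steps (folds, permutations, bootstraps, the
  generator) take explicit seeds; `run_pipeline()` derives stage seeds
  deterministically from one master seed and records them in the run
  log together with exclusion counts.

## Problem sizes used in the validation suite

The simulation-based checks run at sizes chosen to give stable
Monte-Carlo estimates while remaining quick on a laptop: the
family-wise error rate is estimated over 500 null cohorts of 38
participants with 1,000 permutations each; bootstrap-selection
recovery over 50 runs at n = 200 with 1,000 resamples (the analysis
default of 10,000 resamples is used for real runs, where the answer
must be stable rather than repeatedly re-estimated); and the
ergodicity contrast over 100 cohorts per regime of 25 participants ×
12 windows. At these sizes the binomial error of the estimated rates
is 1–5 percentage points, which the corresponding tolerances reflect.

## Known limitations

* The generator's single shared latent state makes the three targets
  mutually more correlated than real symptom scales; the multi-target
  model consequently looks better on synthetic data than it would in
  the field.
* Pairwise deletion in the screening stage assumes missingness
  unrelated to the feature–symptom link (plausible for "did not blog
  this fortnight", less so for "did not complete the assessment").
* The within-subject stage treats windows as exchangeable; it does not
  model autocorrelation, and the t-test on mean Fisher z is exact only
  under normality of the per-participant z values.
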