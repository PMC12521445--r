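---
title: "Methods: meta-analysis of grassland root decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: meta-analysis of grassland root decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`rootmeta` synthesizes paired treatment/control measurements of root
litter mass loss across many field studies. This vignette documents the
statistical model, the harmonization conventions, the synthetic-data
generator that backs the test suite, and the numerical and design choices
a maintainer should know about.

## Data model and harmonization

An observation is one treatment/control pair at one time point: group
means of mass loss (percent of initial dry mass, 0–100), dispersion
values with a label (`sd`, `se`, `ambiguous`, `missing`), replicate
counts, a factor code (one of twelve manipulations, or `control_only`
for unpaired ambient rows), decomposition duration in months, and
optional moderators (geography, climate, initial litter chemistry,
litterbag geometry).

Literature-extracted tables are messy in three specific ways, each with a
fixed harmonization rule:

* **Missing dispersion.** When neither SD nor SE is reported, the SD is
  imputed as one tenth of the group mean. This is the standard
  convention in decomposition meta-analysis; it makes imputed
  observations neither dominant nor negligible in the weighting.
* **Ambiguous dispersion.** A value whose type is unclear is treated as
  a standard error and multiplied by `sqrt(n)` — the conservative choice,
  since it inflates rather than shrinks the assumed sampling variance.
  The `ambiguous` label is kept distinct from `se` so ingest reports can
  audit how often the assumption was invoked.
* **Decay constants.** Studies reporting only a rate constant `k` are
  converted through the single negative exponential
  `mass loss = (1 − e^{−k t}) × 100` with `t` in years. A single-pool
  model is the universal convention for such conversions; `k` is stored
  per year, duration in months, so the conversion factor is 12.

Rows without a duration, flagged as non-root substrate, or flagged as
violating non-replacement sampling are dropped with per-reason counts.
Harmonization is idempotent: resolved SDs are relabelled `sd`, so a
second pass changes nothing.

## Effect sizes and pooling

The effect size is the log response ratio `ln(X_t/X_c)` with
delta-method variance `v = S_t²/(n_t X_t²) + S_c²/(n_c X_c²)` and weight
`w = 1/v`. `v` is scale-free, so storing mass loss as percent rather
than fraction has no effect on the weighting.

Pooling per factor is heterogeneity-gated: a fixed-effects weighted mean
is computed first, and the mixed-effects (random-effects) model replaces
it only when the Q test rejects homogeneity at `alpha = 0.05`. The
between-study variance uses the DerSimonian–Laird moment estimator
`τ² = max(0, (Q − df)/(Σw − Σw²/Σw))`. No estimator is canonical for
this literature's software lineage; DL is the classical default of that
generation, is closed-form (which matters inside the bootstrap), and is
cross-checked against `metafor` in the test suite. REML/ML estimators
are deliberately out of scope.

Interval estimation is a bias-corrected (BC, not BCa) bootstrap: effects
are resampled with replacement, the *entire* selection pipeline (fixed
fit, Q test, τ², mixed re-fit) is re-run on every resample, and the
percentile endpoints are shifted by `z₀ = Φ⁻¹(#{θ*_b < θ̂}/B)` (strict
inequality; a proportion of 0 or 1 is clamped to `1/(2B)` before the
probit). The default is `B = 64,999`; the internal resampling is
vectorised over a `k × B` matrix, so production-size bootstraps take
seconds. The resampling unit is the individual observation, matching the
observation-level weighting of the pooled estimate; a study-level
cluster bootstrap is available via `unit = "study"` for sensitivity
analysis. An effect is significant when the BC interval excludes zero.
Note that BC intervals need not contain the point estimate under extreme
skew; the code only guarantees `ci_low ≤ ci_high`.

**Zero-variance floor.** Because the mean/10 imputation makes genuinely
zero dispersion an artifact of reporting, observations where both
resolved SDs are zero receive `v = 1e-8` (with a warning) instead of
infinite weight.

## Subgroups, meta-regression, publication bias

Duration subgroups use half-open bins with default edges
`{4, 6, 12, 18, 24}` months — reconstructed from the decomposition stages
at which treatment effects typically shift, and always configurable
since no canonical binning exists. A bin is pooled only if it contains
data from at least 3 independent studies (distinct `study_id`s) or at
least 10 observations. Over the included bins the fixed-effects
heterogeneity statistic partitions exactly:
`Q_total = Q_between + Σ Q_within`, with `Q_between` tested on
chi-square(G−1).

Meta-regression fits lnRR on one continuous moderator by weighted least
squares with random-effects weights `1/(v + τ²)`, where `τ²` is the
method-of-moments estimate from the fixed-weights residual
heterogeneity, `τ² = max(0, (Q_E − (k − 2))/tr(P))` with
`P = W − WX(X'WX)⁻¹X'W` — the moderator-adjusted analogue of DL, reducing
to it for an intercept-only design. The moderator test is
`Q_M = (β/se)²` on chi-square(1). Time-dependence screening is exactly
this regression with `duration_months` as the moderator. Multi-moderator
models are out of scope.

Publication-bias robustness uses the Rosenthal fail-safe number with a
one-tailed critical value `z_c = Φ⁻¹(0.95)`:
`N_fs = max(0, (Σ z_i)²/z_c² − k)` with `z_i = lnRR_i/√v_i`, compared
against the `5n + 10` threshold with a *strict* inequality (ties are
reported as not robust). Rosenthal rather than Orwin is the variant
behind "fail-safe numbers" in this literature; the test suite checks it
against a brute-force oracle that appends null studies until the
Stouffer combined z drops below the critical value.

## Variance partitioning on ambient data

The driver-importance stage uses ambient-condition mass loss — every
row's control group, including controls of manipulation experiments —
as the response. Predictor sets are geoclimate (latitude, longitude,
elevation, MAT in °C, MAP in mm/yr) and litter quality (AUR, C, N, P in
percent of dry mass; AUR:N and C:N ratios); decomposition duration is
always retained as a predictor since mass loss is cumulative. Matrices
are complete-case: chemistry missingness is structural (AUR is only
comparable across studies using the acid-unhydrolyzable-residue method),
so imputation would fabricate data. The temporal split at 12 months
places the boundary in the early (`≤ 12`) group.

Random forests (default 500 trees, one third of predictors per split)
report the out-of-bag pseudo-R² `1 − MSE_oob / Var(y)`. Permutation
importance significance follows the response-permutation scheme: the
null distribution of each predictor's `%IncMSE` comes from refitting the
forest with the response shuffled, and the p-value uses the add-one rule
`(1 + #{null ≥ obs})/(n_perm + 1)`, so it is never exactly zero. Default
`n_perm = 100`, configurable.

"Mean contribution" of a predictor group is the arithmetic mean of its
members' permutation importances; how raw importances should be scaled
into contribution percentages is genuinely underdetermined, so the
scaling is a switch — `group_mean_contribution(..., scale_to_r2 = r2)`
rescales importances to sum to the model's explained variance before
averaging, which is what the pipeline reports.

Hierarchical partitioning (Chevan–Sutherland) runs on group composites:
each group is collapsed to its first principal component (columns
standardized; sign anchored so the N loading is positive for quality and
the MAT loading positive for geoclimate, making orientations
reproducible), and each group's independent contribution is the average
R² increment over all orders of entry, computed from all-subsets linear
fits. Contributions telescope to the full-model R²; the test suite
verifies agreement with an exhaustive ordering-enumeration oracle to
1e-10 for up to four groups.

## The synthetic-data generator

There is no deposited compilation of this literature, so the package
ships a generator that emulates the *statistical structure* the analysis
assumes, with every parameter recorded as ground truth:

* **Sites** (default 69): temperate latitude bands ±[25°, 55°], MAT
  decreasing with |latitude| (`28 − 0.6|lat|` + noise, °C), MAP
  log-normal with median ≈ 400 mm/yr.
* **Chemistry:** N log-normal (median 0.8 % of dry mass, clipped to
  0.3–2.5), AUR normal (25 ± 7 %, truncated above 5 via inverse-CDF so
  draws stay seed-stable), C ≈ 42 ± 3 %, P log-normal (median 0.09 %);
  ratio columns computed, never drawn.
* **Decay model:** `ln k = 0.12 + 0.6 ln(N) − 0.8 (AUR/25) +
  0.15 (MAT/10) + 0.2 (MAP/1000) + u_site`, `u_site ~ N(0, 0.3)`. The
  signs encode the established qualitative findings (N accelerates, AUR
  retards, warmth and moisture accelerate); the intercept is calibrated
  so median one-year ambient mass loss is ≈ 40 %, a typical grassland
  value, and the test suite checks that calibration by simulation.
* **Treatment effects:** per-factor true percent changes default to the
  magnitudes and directions reported for these twelve factors in the
  grassland root-decomposition literature (between +16.3 % for P
  addition and −27.8 % for vegetated soil); study effects are
  `δ_s ~ N(true lnRR, τ)` with `τ = 0.08` (moderate between-study
  heterogeneity). Observed group means get sampling error
  `N(0, (cv·mean)²/n)` with `cv = 0.10` and 3–5 replicates, so the
  delta-method `v` is correctly specified by construction.
* **Reporting mess:** dispersion values are blanked with probability
  0.20 and mislabelled as ambiguous SEs with probability 0.10,
  exercising the harmonization rules end to end.
* Default sizes — 24 studies/factor × 4 observations ≈ 1,150 pairs plus
  ~340 unpaired ambient rows — mirror the scale of published compilations
  of this literature.

Random streams are split per component (sites / chemistry / study
effects / noise), so changing one count does not perturb the others'
draws, and output is byte-identical under a fixed seed.

What the generator does **not** emulate: real covariate correlation
structure beyond the decay model (e.g. climate–chemistry covariance
through shared species pools), serial correlation of repeated
measurements within a litterbag series, non-log-linear treatment
effects, and publication bias itself. Passing recovery tests therefore
demonstrates that the estimators are correct under the stated model, not
that the model captures every feature of field data. Treatment means are
clipped at 99.9 % mass loss (with a warning), which mildly attenuates
large positive effects at long durations — visible, and intentional,
since percent mass loss is physically bounded.

## Numerical choices and degenerate inputs

* Pooling requires `k ≥ 2`; the bootstrap requires `B ≥ 999` and returns
  a degenerate `[x, x]` interval (with a warning) when all resample
  estimates coincide.
* `τ²` is truncated at zero; a degenerate weight distribution (all
  weight on one effect) yields `τ² = 0` with a warning.
* Observations with a nonpositive group mean are excluded from effect
  sizes (the log ratio is undefined) and counted in the ingest report.
* Duration bins are half-open `[e_i, e_{i+1})`, below-first-edge values
  form a `<e_1` bin, and the last bin is open-ended.
* PCA composites fail loudly on zero-variance columns rather than
  silently dropping them.
* The Gaussian fit of each factor's effect distribution is the ML
  normal fit (denominator `n`); `σ = 0` is flagged, not an error.

## Problem sizes in the test and acceptance runs

The test suite uses reduced sizes chosen to keep the statistical checks
well-powered while running in about a minute: bootstrap checks at
`B = 999–9,999`, forests at 60–200 trees, calibration experiments at
300–2,000 replicates, and recovery at 40 studies/factor over 20 seeds.
The acceptance script runs the pipeline at full production settings
(`B = 64,999`, 500 trees) on the default-size dataset, with `n_perm = 30`
response permutations per temporal subset for importance significance —
enough for stable group-level contrasts, which is all the report uses
them for.

## Known limitations

* The mixed-effects machinery is DL + inverse-variance weighting; exact
  numerical agreement with any particular GUI meta-analysis program is
  not guaranteed.
* Whether historical analyses of this literature resampled observations
  or studies in their bootstrap is not documented; both are implemented,
  observation-level is the default.
* Hierarchical partitioning is the linear, PC1-composite variant; no
  mixed-model partitioning.
* Effect metrics other than the log response ratio (Hedges' d, raw mean
  difference) are out of scope, as are funnel plots, trim-and-fill and
  Egger regression.
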