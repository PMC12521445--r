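# rootmeta

Weighted log response-ratio meta-analysis of root litter decomposition in
grassland ecosystems.

Field experiments measure root litter mass loss (percent of initial dry
mass) under paired treatment and control conditions — nitrogen or
phosphorus addition, warming, altered precipitation, elevated CO2,
grazing, vegetated vs bare soil, plant or litter species richness,
home-field vs away decomposition, and soil fauna exclusion. Syntheses of
this literature must harmonize messy reporting (standard deviations vs
standard errors vs nothing at all; decay constants instead of mass loss),
weight observations by their sampling precision, and separate treatment
effects from the large background variation driven by litter chemistry
and climate. `rootmeta` implements that entire workflow for
meta-analysts and decomposition ecologists, with a seeded synthetic-data
generator so every stage can be validated against known ground truth.

## The statistics

For each observation pair the effect size is the log response ratio

    lnRR = ln(X_t / X_c)

with delta-method sampling variance and inverse-variance weight

    v = S_t^2 / (n_t X_t^2) + S_c^2 / (n_c X_c^2),    w = 1 / v

where `X`, `S`, `n` are each group's mean mass loss, SD and replicate
count. Per factor, a fixed-effects weighted mean `RR++ = Σ w_i lnRR_i / Σ
w_i` is computed first; if the heterogeneity statistic
`Q = Σ w_i (lnRR_i − RR++)^2` is significant against chi-square(k−1), a
mixed-effects model re-estimates `RR++` with weights `1/(v_i + τ²)`,
where `τ²` is the DerSimonian–Laird moment estimator. Significance comes
from a bias-corrected bootstrap confidence interval (64,999 resamples by
default, full model re-selection inside every resample), and effects are
reported as percent change `(e^{RR++} − 1) × 100`. The surrounding stages
are duration-binned subgroup analysis with Q partitioning, weighted
meta-regression on continuous moderators, Rosenthal fail-safe numbers
against the `5n + 10` robustness threshold, and a variance-partitioning
stage on ambient-condition data: random-forest explained variance and
permutation importances for geoclimatic vs litter-quality predictors,
PCA-composite hierarchical partitioning, and trait–mass-loss
correlations.

## Worked example

```r
library(rootmeta)

obs  <- generate_meta_dataset(seed = 42)   # ~1,150 pairs, 12 factors, 69 sites
harm <- harmonize(obs)                     # SD imputation, SE conversion, k -> mass loss
eff  <- compute_effect_sizes(harm)         # lnRR, v, w per observation

fit <- pool_effects(eff[eff$factor == "warming", ], b = 64999, seed = 42,
                    factor = "warming")
print(fit)
#> Pooled effect for factor 'warming'
#>   k = 96 observations, mixed-effects model (Q = 286.978, df = 95, p = 3.7e-21)
#>   RR++ = 0.0644  [0.0429, 0.0856] (BC bootstrap, B = 64999)
#>   tau2 = 0.00711;  percent change = +6.65%  *
```

The heterogeneity test rejects homogeneity (p ≈ 4e-21), so the pooled
estimate comes from the mixed-effects model with between-study variance
τ² ≈ 0.0071. The bias-corrected bootstrap interval [0.043, 0.086]
excludes zero, so warming significantly accelerates decomposition — here
by +6.65% — against a generator ground truth of +9.8% for this factor
(the gap reflects study-level heterogeneity in a single replicate
dataset). The fail-safe check for the same factor:

```r
fail_safe(eff[eff$factor == "warming", ], factor = "warming")
#>    factor n_obs     n_fs threshold robust
#> 1 warming    96 3785.577       490   TRUE
```

3,786 hypothetical null studies would be needed to overturn the result —
far above the `5·96 + 10 = 490` threshold. `run_pipeline(pipeline_config(...))`
executes all stages and writes per-stage CSVs plus a consolidated
`report.json` and run manifest.

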