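Package: rootmeta
Title: Meta-Analysis of Grassland Root Litter Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for weighted log response-ratio meta-analysis of root
    litter decomposition experiments in grasslands. Harmonizes
    literature-style mass-loss observation tables (dispersion imputation,
    standard-error conversion, decay-constant recalculation), computes
    per-observation effect sizes and inverse-variance weights, pools them
    per experimental factor with a heterogeneity-gated fixed/mixed-effects
    model and bias-corrected bootstrap confidence intervals, runs
    duration-grouped subgroup analyses and single-moderator
    meta-regressions, checks robustness with Rosenthal fail-safe numbers,
    and partitions decomposition variance between litter-quality and
    geoclimatic drivers via random forests, PCA composites and
    hierarchical partitioning. A seeded synthetic-data generator produces
    multi-study datasets with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
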