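Package: crossnobis
Title: Cross-Validated Mahalanobis RSA for Imagined and Perceived Stimuli
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for representational similarity
    analysis (RSA) of imagery and perception fMRI experiments that use
    continuous carry-over designs. Builds serially balanced stimulus
    sequences and trial timelines, simulates multi-voxel activity patterns
    and BOLD time series with spatially correlated noise, estimates
    per-condition patterns by ordinary least squares with a framewise
    displacement nuisance regressor, computes cross-validated Mahalanobis
    (crossnobis) representational dissimilarity matrices with multivariate
    noise normalization via shrinkage covariance estimation, averages
    distances over factor-defined condition pairs with a two-standard
    deviation exclusion rule, and runs a two-stage region-gated testing
    framework (one-sample gates with seed-level Bonferroni correction,
    followed by paired/two-sample t tests or one-way ANOVA).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    RNifti,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
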