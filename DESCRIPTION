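Package: discopad
Title: Distance-Correlation-Based Effective Number of Tests for
    Metabolome-Wide Association Studies
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Single-step multiple-testing correction for correlated omics
    features via the effective number of tests (Meff). Builds Pearson,
    Spearman, or distance-correlation association matrices over features,
    repairs them to the nearest positive semidefinite matrix, and applies
    five eigen-analysis Meff estimators (Nyholt, Li-Ji, Gao, Galwey,
    Peluso) plus Bonferroni/Sidak baselines to derive pointwise
    significance levels at a target family-wise error rate. Includes a
    fast O(n log n) univariate distance covariance, a permutation-based
    gold standard for the pointwise error rate, covariate-adjusted
    per-feature testing (linear regression, Welch t), synthetic data
    generators, a simulation/RMSE benchmarking harness, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
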