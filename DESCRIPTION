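Package: cealmm
Title: Linear Mixed Models for Trial-Based Cost-Effectiveness Analysis with
    Missing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for trial-based cost-utility analysis when utility and cost
    outcomes are partially missing. Fits mixed models for repeated measures
    (MMRM) by direct maximization of the observed-data multivariate-normal
    likelihood, which is valid under missing at random; forms quality-adjusted
    life years and total costs as linear combinations of the fitted
    coefficients; quantifies uncertainty by a stratified nonparametric
    bootstrap; and summarizes decisions with incremental cost-effectiveness
    ratios, cost-effectiveness planes and acceptability curves. Includes a
    complete-case comparator, baseline mean-imputation, and a synthetic
    two-arm trial generator with configurable missingness mechanisms.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    nlme,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
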