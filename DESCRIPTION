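Package: bwmr
Title: Two-Sample Mendelian Randomization of Birth Weight on Ischemic Heart
    Disease and Lipids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization with GWAS summary
    statistics, built around the analysis of genetically predicted birth
    weight on ischemic heart disease, myocardial infarction and blood lipids.
    Implements per-SNP Wald ratio estimates with Fieller's-theorem confidence
    intervals, fixed-effect inverse-variance-weighted pooling, MR-Egger
    regression with the directional-pleiotropy intercept test, and weighted
    median estimation with a parametric-bootstrap standard error and a
    dominant-instrument availability guard. Includes allele harmonization for
    exposure and outcome summary tables, the named instrument subsets used in
    the sensitivity analyses, a full outcome-by-source-by-subset-by-method
    sensitivity grid with funnel and forest data export, unit conversion
    between per-standard-deviation and per-100-gram scales, and a synthetic
    two-sample summary-statistics generator with known causal effect and
    pleiotropy regimes for validating every estimator without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
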