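Package: qsarcons
Title: Consensus QSAR Evaluation with Uncertainty-Based Outlier and
    Substructure Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating ensembles of QSAR regression models on a
    common endpoint: unweighted consensus predictions with and without
    applicability-domain (AD) constraints, AD stringency sweeps, regression
    metrics with bootstrap confidence intervals, distance-to-model binning
    (bin-based averaging) for uncertainty-calibrated outlier detection with
    Williams-plot export, substructure-conditional prediction-error
    significance via a rescaled-error bootstrap null with Benjamini-Hochberg
    control, functional-group enrichment-factor analysis, and
    fingerprint-based Tanimoto similarity diagnostics. A synthetic ensemble
    generator with planted outliers and substructure effects makes every
    stage testable without proprietary model predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
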