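Package: orbsel
Title: Selection Models for Outcome Reporting Bias in Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Adjusts random-effects meta-analyses for outcome reporting bias
    (ORB) with parametric selection models. Unreported study outcomes, whose
    sample sizes are known but whose effects and standard errors are missing,
    contribute to a weighted likelihood through a selection function of the
    one-sided p-value; missing variances are imputed from the reported
    studies' design factor. Provides maximum-likelihood estimation of the
    pooled effect and heterogeneity variance with profile-likelihood
    confidence intervals, a Monte-Carlo simulation engine for
    missing-not-at-random outcome reporting with MCAR benchmarks and
    Morris-style performance measures, sensitivity analysis over selection
    function parameters, and the Topiramate add-on epilepsy meta-analysis as
    a worked example.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
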