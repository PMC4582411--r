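Package: vitdmr
Title: Mendelian Randomisation of Vitamin D Status and Blood Pressure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for allele-score Mendelian
    randomisation of 25-hydroxyvitamin D concentration against systolic and
    diastolic blood pressure and hypertension risk. Covers multi-cohort
    simulation of confounded biomarker-outcome data, phenotype preparation
    (antihypertensive treatment correction, hypertension classification,
    natural-log biomarker scale), unweighted synthesis and metabolism allele
    scores with GWAS summary-statistic harmonisation, per-study adjusted
    regressions, fixed- and random-effects meta-analysis with heterogeneity
    diagnostics and univariate meta-regression, summary-statistic allele-score
    approximation, and instrumental-variable Wald ratio estimates with
    delta-method (Taylor expansion) variance and instrument-strength
    diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    withr,
    yaml
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
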