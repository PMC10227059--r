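Package: comorbscreen
Title: Stratified Comorbidity Screening and Time-Order Analysis for
    Hospital Diagnosis Registries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening pairwise diagnosis associations in
    longitudinal inpatient registries coded with level-3 ICD-10 codes.
    Implements washout-based cohort selection, age-decade by calendar-window
    stratification, Mantel-Haenszel pooled odds ratios with
    Robins-Breslow-Greenland confidence intervals, the Cochran-Mantel-Haenszel
    test, occurrence filtering with Bonferroni-corrected significance calls,
    time-order-ratio directionality analysis with an exact binomial sign test,
    sex-stratified and somatic-exclusion sensitivity analyses, and a synthetic
    registry generator with known injected effect sizes for validation.
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
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
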