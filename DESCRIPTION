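Package: deweight
Title: Deweighted Propensity-Score Estimation of Health Care Disparities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates health care disparities concordant with the Institute
    of Medicine definition: group differences in care should be adjusted for
    health status and clinical need but not for socioeconomic status (SES).
    Subjects are weighted by balancing weights built from a full propensity
    score and then deweighted by balancing weights built from an SES-only
    propensity score, so that health status is balanced conditional on SES
    while each group's marginal SES distribution is preserved. Provides
    maximum-likelihood and just-identified covariate-balancing propensity
    score (CBPS) fitting, optionally stratified by SES subgroup; ATE, ATT and
    ATO disparity estimands with Hajek estimators and linearization or
    bootstrap confidence intervals; absolute standardized mean difference
    diagnostics for SES preservation and within-subgroup health-status
    balance; weighted target-population characteristics; and a synthetic-data
    generator with analytically known propensity scores for validation.
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
    purrr,
    readr,
    rlang (>= 1.0.0),
    stats,
    tibble,
    tidyr,
    tidyselect,
    utils
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
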