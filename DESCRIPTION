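Package: rppclc
Title: Robust Privacy-Preserving Models for Cluster-Level Confounding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates observed and unobserved cluster-level confounding from
    provider-level summary statistics alone (observed and expected outcome
    counts, effective sizes, and cluster covariates), without access to
    patient-level records. Naive fixed-effects Z-scores are modelled with a
    robust truncated-normal empirical-null likelihood to recover the observed
    confounding effects, the overdispersion due to unobserved cluster-level
    heterogeneity, and the null proportion. Outlying providers are then
    flagged either with corrected frequentist Z-scores or with a
    pseudo-Bayesian posterior for the indirectly standardized measure ratio,
    a Gamma-lognormal mixture that propagates the uncertainty in the
    confounding estimates. Includes synthetic-data generators and Monte-Carlo
    study drivers for estimation, correlated-random-effects, and
    flagging/coverage experiments.
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
    MASS,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
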