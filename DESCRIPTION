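Package: isoniche
Title: Individual Specialization and Repeatability from Repeated Stable Isotope Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies individual foraging specialization from repeated
    stable-isotope measurements (delta 13C and delta 15N) of marked animals
    sampled across multiple years. Decomposes the population's total isotopic
    niche width (TNW) into within-individual (WIC) and among-individual (AIC)
    components and reports the WIC/TNW specialization ratio; estimates
    among-year repeatability (intraclass correlation) from REML variance
    components with parametric-bootstrap standard errors and
    boundary-corrected likelihood-ratio tests; and fits Gaussian linear mixed
    models with crossed individual and year random intercepts (and optional
    individual random slopes) that separate within-individual from
    among-individual covariate effects via within-subject centering,
    reporting AIC model comparisons and marginal/conditional R-squared.
    Includes a synthetic-data generator that emulates a multi-year,
    unbalanced seabird sampling design so the whole pipeline can be
    exercised and validated by simulation.
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
    lme4,
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
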