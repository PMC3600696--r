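Package: f2qg
Title: Quantitative Genetics of F2 Intercross Resource Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pedigree-based quantitative-genetic analysis of F2 intercross
    resource populations, built around the divergent-founder pig obesity
    design. Provides pedigree parsing and validation, the additive
    relationship matrix and its sparse Henderson inverse, univariate and
    bivariate animal-model REML (EM warm start plus average-information
    updates) with delta-method standard errors for heritabilities and
    genetic/phenotypic correlations, BLUP breeding values, derived obesity
    traits (lean-meat percentage, BMI, body adiposity index, daily gains),
    a gene-drop simulator that emulates the three-generation F2 design, and
    analytic QTL-detection power for F2 crosses including a liability-scale
    conversion for categorical traits.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
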