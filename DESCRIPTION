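Package: silerfit
Title: Bayesian Siler Survivorship Models for Age-Frequency Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits nested Siler-type competing-hazard survivorship models
    (constant, maturation, senescence and their combinations) to standardized
    age-at-capture frequency data, such as tooth-cementum annuli counts from
    bat colonies, in a Bayesian framework with adaptive Metropolis MCMC.
    Provides DIC-based model selection, annual survival and life-expectancy
    summaries, predicted age structures under a stable age distribution with
    population growth, sensitivity analysis to the growth-rate assumption,
    ordinary least-squares regression of survival on colony covariates, and a
    synthetic colony generator for end-to-end testing of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble
Suggests:
    coda,
    rjags,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
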