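Package: telovar
Title: Hierarchical Covariance Decomposition of Telomere Length, Helminth
    Infection, Immunity and Survival in Longitudinal Field Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for asking whether leucocyte relative telomere length
    covaries with helminth infection burden, parasite-specific antibody
    levels and overwinter survival in longitudinal individual-based field
    studies. Provides assay-level trait computation (qPCR relative telomere
    length with triplicate quality control, ELISA optical-density ratios
    with duplicate and plate-pair quality control, McMaster faecal egg
    counts), Bayesian univariate and multivariate generalized linear mixed
    models with unstructured among-individual, among-year and residual
    covariance matrices fitted by a purpose-built parameter-expanded Gibbs
    sampler, covariance-derived correlations, repeatabilities and partial
    regressions of survival on the other traits, and a synthetic-data
    generator with known ground truth for end-to-end validation.
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
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    coda,
    lme4,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
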