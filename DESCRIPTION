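Package: fakemix
Title: Response-Time-Based Mixture IRT Modeling of Faking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits a person-by-item latent response mixture item response
    theory model of faking in high-stakes personality assessments. Item
    responses arise from one of three response strategies per person-item
    pair (substantive-trait-only, trait-plus-faking, faking-only), modeled
    as constrained multidimensional nominal response models with item- and
    category-specific scoring weights; item-level response times follow
    class-specific log-normal models; and a partial credit latent response
    model governs strategy membership. Includes a synthetic-data simulator
    mirroring the model's generative structure, Bayesian estimation of the
    full model and reduced comparison models via an adaptive
    Metropolis-within-Gibbs sampler over the class-marginalized likelihood,
    posterior class probabilities and strategy-consistency summaries,
    parameter-recovery metrics, and model-fit assessment (WAIC, PSIS-LOO,
    posterior predictive SRMR and response-time checks).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    MASS,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
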