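Package: ltabuild
Title: Model Building for Latent Class and Latent Transition Analysis of
    Categorical Panel Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Maximum-likelihood estimation of latent class (LCA) and latent
    transition (LTA) models for categorical panel data by the EM algorithm,
    with forward-backward recursions over latent statuses, longitudinal
    measurement-invariance and transition-invariance testing by
    likelihood-ratio difference tests, information-criterion model
    comparison (AIC, BIC, CAIC, adjusted BIC), relative entropy, one-step
    covariate models on status prevalences through multinomial logits, and
    a staged model-building workflow (cross-sectional candidate pool,
    invariance tests, status definition, covariates).  Includes a synthetic
    panel generator with status-specific item-response probabilities,
    Markov transitions and monotone attrition, plus readers and writers for
    wide and long delimited panel files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nnet,
    withr,
    yaml,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
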