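Package: lineagescan
Title: Detecting Exceptional Trait Evolution Along a Focal Lineage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Bayesian phylogenetic comparative tools for asking whether a
    single species has undergone exceptional evolutionary change in
    continuous traits. Implements reversible-jump MCMC over phylogenetic
    generalized least squares regressions with Pagel's lambda, phylogenetic
    prediction of a held-out target species with outlier probabilities under
    false-discovery-rate control, a multi-optimum Ornstein-Uhlenbeck model
    with a body-mass covariate for detecting adaptive-regime shifts on a
    focal branch, Brownian-motion simulation machinery with lineage-specific
    rate multipliers for false-positive/false-negative validation, and a
    species-wide outlier scan with a logit-proportion meta-analysis.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
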