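Package: kinace
Title: Bivariate ACE Models for Twin and Sibling Data with a Registry
    Survival Stage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the co-occurrence of two traits in
    kinship-structured cohorts. Simulates twin (MZ/DZ) and sibling
    (full and maternal half-sibling) pairs under a bivariate
    additive-genetic (A), shared-environment (C), nonshared-environment
    (E) covariance structure, binary diagnoses via a liability-threshold
    model, item-level psychometric scales, and registry-style follow-up
    with a time-varying exposure on the age timescale. Fits bivariate
    ACE models by maximum likelihood in the direct-symmetric
    parameterization (continuous full-information and binary
    liability-threshold likelihoods), performs likelihood-ratio and AIC
    model selection, and derives standardized variance shares, genetic
    and environmental correlations, and covariance decompositions. A
    phenotypic stage provides Cox proportional-hazards regression with
    delayed entry and time-varying exposure, Kaplan-Meier cumulative
    incidence, and standardized linear regression with cluster-robust
    standard errors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    mvtnorm,
    survival,
    numDeriv,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sandwich
Config/testthat/edition: 3
RoxygenNote: 7.3.3
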