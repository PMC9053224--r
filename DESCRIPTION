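Package: sidefx
Title: Aetiology of Antidepressant Side Effects: Co-Occurrence, Liability
    Modelling and Polygenic Risk
Version: 0.1.0
Authors@R:
    person("Pipeline", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for studying the aetiology of
    self-reported antidepressant side effects. Implements descriptive
    epidemiology of per-medication side-effect endorsement (Wilson
    confidence intervals, two-sample Z proportion tests, two-sample
    t-tests), tetrachoric-correlation estimation of side-effect
    co-occurrence with minimum-variance hierarchical clustering, bifactor
    liability-threshold structural models (general plus SSRI and SNRI
    drug-class factors) fitted by marginal maximum likelihood with
    Gauss-Hermite quadrature, and polygenic risk scoring by clumping and
    thresholding with logistic-regression association testing and
    Nagelkerke pseudo R-squared. A synthetic-cohort generator reproduces
    the statistical structure the analyses assume (liability-threshold
    bifactor endorsements, exposure-driven missingness, block-LD
    genotypes feeding a true polygenic component) so the full chain is
    testable without access-restricted data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    statmod,
    numDeriv,
    optparse
Config/testthat/edition: 3
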