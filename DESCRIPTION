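Package: cagecor
Title: Intra-Cage Correlation and Design of Cluster-Randomized Murine Aging Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying and accommodating outcome dependence among
    co-housed animals in preclinical aging studies. Estimates the intra-cage
    (intra-class) correlation of lifespan and longitudinal phenotypes by three
    routes (moment/ANOVA, random-intercept REML, and exchangeable
    working-correlation GEE), attaches parametric- and cluster-bootstrap
    confidence intervals, and tests significance against a cage-permutation
    null. A Monte Carlo engine quantifies the type-I-error and power
    consequences of ignoring co-housing, and a closed-form calculator inflates
    two-sample sizes by the cluster design effect for cage-randomized trials.
    A synthetic-cohort generator with known ground-truth correlation
    (including negative, via direct factorization of the exchangeable
    covariance) makes every stage testable without access to the original
    colony data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    survival,
    jsonlite,
    yaml
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
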