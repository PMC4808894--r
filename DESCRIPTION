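Package: usualintake
Title: Simulation Study of Usual Dietary Intake Distribution Estimators
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates usual (long-term average) dietary intake
    distributions of daily-consumed nutrients from repeated 24-hour
    recalls, and evaluates the estimators by Monte-Carlo simulation.
    Implements three estimators in the style of the NCI amount model,
    the Multiple Source Method (MSM) and SPADE: a Box-Cox
    transformation to normality, a one-way random-effects variance
    decomposition into within- and between-person components, and
    back-transformation to the original scale by Gauss-Hermite
    quadrature, a 9-point pseudo-person approximation, or a closed
    moment formula with shrinkage of person means. Includes the exact
    (quadrature) truth oracle for the generating Box-Cox model, a
    12-scenario synthetic data generator with reproducible per-person
    random substreams, and a bias / relative bias / MSE evaluation
    harness with Bonferroni confidence intervals and the
    zero-between-variance sample exclusion rule.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    dplyr
Config/testthat/edition: 3
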