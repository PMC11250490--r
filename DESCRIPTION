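Package: aaiiw
Title: Multiply Robust Marginal Structural Models under Irregular
    Covariate-Driven Observation Times
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimation of the marginal causal effect of a time-varying
    binary treatment on a continuous longitudinal outcome that is only
    observed at irregular, covariate-driven visit times, as in electronic
    health records. Implements the doubly augmented, doubly inverse
    weighted (AAIIW) estimating equations, which remain consistent when
    any one of four stated combinations of nuisance models (treatment
    propensity, visit intensity, and two conditional outcome means) is
    correctly specified, together with the ordinary least squares,
    inverse-probability-of-treatment weighted, and doubly weighted (FIPTM)
    comparators, optional inverse-probability-of-censoring weights for
    informative dropout, a synthetic cohort generator with known true
    effect, subject-level bootstrap confidence intervals, Rubin's rules
    pooling, and a Monte Carlo simulation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
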