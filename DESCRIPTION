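Package: meritindex
Title: Selection Index Theory for Multi-Trait Breeding Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for designing and auditing total merit indices in
    multi-trait breeding programs. Given genetic parameters (correlations,
    standard deviations, heritabilities), reliabilities of estimated
    breeding values and relative economic weights, the package solves the
    selection index normal equations, predicts the composition of the
    expected genetic and phenotypic trend (including correlated response in
    non-index traits), de-regresses an empirical covariance matrix of
    estimated breeding values into the covariance of their estimation
    errors, quantifies the sensitivity of the genetic trend to marginal
    changes in economic weights, and inverts an observed genetic-trend
    composition into realized index and economic weights ("index in
    retrospect"). Parameter sets for the German Holstein total merit
    indices used before and after April 2021 are included, together with a
    Monte-Carlo population simulator for validating analytical predictions
    under truncation selection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
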