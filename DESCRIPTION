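Package: jointmarg
Title: Marginal Overall Treatment Effects in Joint Models for
    Longitudinal and Survival Data
Version: 0.1.0
Authors@R:
    person("Floor", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint models for a Gaussian longitudinal outcome and a
    time-to-event outcome link the two processes through shared random
    effects, so the overall treatment effect on the hazard -- the
    aggregate of the direct effect and the indirect effect through the
    longitudinal trajectory -- is conditional on the random effects and
    has a subject-specific interpretation.  jointmarg fits such joint
    models by maximum likelihood with pseudo-adaptive Gauss-Hermite
    quadrature, marginalizes the subject-specific hazards over the
    random-effects distribution by Monte Carlo integration with
    Gauss-Kronrod survival evaluation, and projects the marginal log
    hazards onto the model design by least squares to obtain
    population-averaged coefficients, time-varying hazard-ratio curves,
    weighted-average effects, and Monte-Carlo standard errors.  Current
    value, slope, and cumulative association structures are supported,
    along with a simulator for synthetic trial data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    splines,
    jsonlite,
    survival,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
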