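Package: smoltsar
Title: Carryover Effects on Smolt-to-Adult Survival of Snake River Chinook Salmon
Version: 0.1.0
Authors@R: person("Columbia Basin Survival Modelling", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing juvenile-to-adult ("smolt-to-adult") survival
    of PIT-tagged spring/summer Chinook salmon as a function of migration
    timing, freshwater, marine and climate covariates.  Provides a synthetic
    cohort simulator with known parameters, covariate engineering (rolling
    means, residualization, binary PDO phase index, standardization), a
    Bernoulli/logit mixed-effects survival model fitted by Laplace-approximated
    maximum likelihood with independent year-level random intercept and
    migration-timing slopes, AICc-based multimodel averaging over an
    all-subsets candidate space with hierarchy constraints, and parametric
    simulation of the differential delayed mortality statistic D (ratio of
    transported to run-of-river survival) across cool/warm ocean phases.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse,
    withr
Config/testthat/edition: 3
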