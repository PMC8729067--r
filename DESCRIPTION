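Package: migchoice
Title: Temporal Discrete-Choice Models of Migration Departure Decisions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the timing of migration departure by
    individually tracked birds as a discrete choice among temporal
    alternatives. Collapses raw telemetry records to daily movements,
    identifies migration-scale relocation events, attaches gridded daily
    weather covariates including cumulative frost-day, snow-day and
    freezing-degree-day ice indices, builds temporal choice sets, and fits
    panel mixed (random-parameters) conditional logit models by maximum
    simulated likelihood, with BIC-based model ranking, leave-one-out
    cross-validation, response-curve prediction and simulation utilities
    for generating synthetic tracks and weather with known parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    ggplot2,
    generics,
    geosphere,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    survival,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
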