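Package: moodcast
Title: Idiographically Weighted Forecasting of Hourly Depressed Mood from
    Passive Smartphone Sensing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting next-hour depressed mood from passively
    sensed smartphone data in ecological momentary assessment (EMA) studies.
    Implements a two-phase modelling pipeline: a pooled (nomothetic)
    gradient-boosted stage whose out-of-fold predictions are stacked as a
    feature into person-weighted (idiographic) random forests, fitted on
    24-hour rolling windows under strict temporal-leakage guards. Includes a
    synthetic cohort generator with known ground-truth sensor-mood couplings,
    chained-equation multiple imputation for hourly sensor panels,
    predicted-versus-observed correlation summaries with Fisher-z averaging
    across persons, and mixed-model sensitivity analyses (race moderation and
    lagged-outcome control).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    parallel,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
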