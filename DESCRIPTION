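Package: sleepcast
Title: Next-Night Sleep Prediction from Wearable Activity, Light and
    Heart-Rate-Variability Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for predicting whether the coming night
    will be a good sleep (sleep efficiency of at least 90 percent) from
    multi-day wrist-wearable recordings.  Raw 10-second triaxial activity
    counts and illuminance are aggregated to 60-second epochs, scored
    sleep/wake with a Cole-Kripke style weighted moving window, and combined
    with sleep-diary entries and pre-sleep heart-rate-variability (pNN50)
    into windowed day-unit features.  A benchmark harness trains gradient
    boosting, convolutional and recurrent networks, and logistic regression
    over a data-source by data-length grid with participant-grouped
    cross-validation, reporting accuracy and AUC per cell.  A synthetic
    cohort generator with a controllable dependence structure (arousal,
    evening activity, late light, night-to-night carry-over) makes every
    stage testable without access to real participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    generics,
    ggplot2,
    jsonlite,
    purrr,
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
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
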