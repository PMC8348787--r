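Package: mpar
Title: Maternal Physical Activity Recognition from Wrist-Worn Sensor Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A toolkit for recognising maternal physical activities from
    wrist-worn accelerometer, gyroscope and temperature streams sampled at
    50 Hz. Provides a delimited-text data model for labelled sensor
    recordings, sliding-window segmentation (1 s or 2 s windows, optionally
    50% overlapped), extraction of a 43-dimension statistical and spectral
    feature vector per window, a multi-classifier evaluation harness with
    repeated stratified train-test splits and confusion-matrix reporting,
    a rule-based monitoring layer that raises alerts when a proscribed
    activity is sustained, and a seeded synthetic signal generator that
    emulates a ten-activity maternal cohort so the whole pipeline is
    testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rpart,
    ranger,
    xgboost,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
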