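Package: postoprecovery
Title: Continuous Postoperative Recovery Scores from Wearable Sensor Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for modelling day-by-day postoperative recovery of
    abdominal-surgery patients from two-device wearable streams. Engineers
    daily reference recovery profiles from length of stay and Clavien-Dindo
    graded complication events, extracts daily vital-sign, heart-rate
    variability, circadian, heart-rate-recovery and activity features from
    chest- and wrist-sensor streams, searches for a covariate-balanced
    train/test split, trains a gradient-boosted regression model with
    Friedman/Nemenyi backward feature elimination, and compares individual
    predicted recovery profiles against fast- and slow-recovering group
    bands. Includes a latent-state synthetic cohort and sensor-stream
    generator so the whole pipeline is testable without clinical data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    xgboost,
    jsonlite,
    yaml,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
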