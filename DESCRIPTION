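Package: alarmscape
Title: Threshold Alarm Patterns in Pediatric Vital-Sign Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing threshold alarms in continuous pediatric
    vital-sign monitoring. Detects contiguous threshold-violation episodes in
    1 Hz heart-rate, respiratory-rate and oxygen-saturation streams using
    WHO or GOAL3 age-specific cut-offs, restricts alarms to the 8 hour
    window preceding critical illness events, extracts modal alarm-pattern
    features per patient and signal with a density-based (DBSCAN) clusterer,
    and trains random-forest, support-vector and decision-tree classifiers
    to distinguish death/CPR/PICU and sepsis events from event-free
    monitoring. Includes a synthetic-cohort generator with age-appropriate
    baselines, sensor dropout, transient artifacts and planted pre-event
    alarm patterns so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    randomForest,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml,
    e1071
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
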