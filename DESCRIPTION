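Package: stagewalk
Title: Stage Classification of Alzheimer's Patients from Smartphone
    Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting stage-dependent differences in the
    free-movement accelerometer curves of Alzheimer's patients and for
    classifying patients into early/middle/late disease stage. Implements
    a synthetic-cohort generator emulating smartphone accelerometer logs
    (irregular ~8 Hz sampling, gravity orientation per recording,
    stationary within-recording dynamics), random-window preprocessing of
    variable-length recordings, three functional equality-of-means tests
    (random-projection ANOVA with Bonferroni/FDR combination, bootstrap
    sup-F ANOVA, bootstrap L2 two-sample test), an h-mode-depth functional
    classifier with leave-one-patient-out evaluation, fixed-width feature
    extraction from variable-length recordings, and patient-grouped
    neural-network and baseline stage classifiers with majority voting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    pracma,
    rpart,
    randomForest,
    e1071,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
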