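Package: vestigait
Title: Vestibular Gait Classification from Body-Worn Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for studying how inertial measurement unit
    (IMU) placement and gait task selection affect automatic screening for
    vestibular deficits. Provides a synthetic multi-IMU gait generator with
    analytic ground truth, sensor-to-body axis alignment by gravity and
    principal component analysis, zero-phase band-pass filtering,
    zero-velocity-update (ZUPT) stride estimation from foot-mounted sensors,
    a 590-feature kinematic descriptor set, subject-wise repeated Random
    Forest evaluation with merged-prediction AUROC and bootstrap confidence
    intervals, and model interpretation through correlated-feature cluster
    permutation importance and Welch t-tests with effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    ranger,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
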