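Package: wearfu
Title: Functional Arm-Use Detection from Wrist-Worn Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects functional versus non-functional arm use of prosthesis
    users and controls from a single wrist-worn six-channel inertial
    measurement unit (three-axis accelerometer plus three-axis gyroscope,
    nominally 200 Hz). Implements two block-segmentation schemes (fixed
    800-sample blocks and variable-length blocks grown by a two-sample
    Hotelling T-squared change detector), block-level features (histogram
    entropy, mean, variance, axis-matched linear-angular cross-correlation),
    a seeded Random Forest classifier with intra-subject 10-fold and
    inter-subject leave-one-subject-out protocols, chunk-size-weighted
    accuracy, functional-use time estimation, and nonparametric group
    statistics. Includes a regime-switching synthetic IMU generator with
    simulated video annotators so the whole pipeline is testable without
    human-subject recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    randomForest,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
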