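Package: apakit
Title: Detection and Quantification of Anticipatory Postural Adjustments
    from Force Plates and Wearable Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Instrumented analysis of anticipatory postural adjustments
    (APAs) preceding gait initiation and step climbing.  Detects APA onset,
    heel-off, toe-off and foot contact of the leading foot from force-plate
    center-of-pressure (COP) trajectories and vertical ground reaction
    forces (the laboratory gold standard), and from a two-unit wearable
    setup (lower-trunk accelerometer, shank gyroscope) using
    threshold-based detectors.  Includes zero-phase Butterworth filtering,
    Moe-Nilssen tilt correction of trunk accelerations, grid-search
    calibration of the inertial thresholds against force-plate events,
    extraction of spatio-temporal APA parameters, validation and
    group-comparison statistics, and a synthetic-trial generator producing
    paired recordings with known ground-truth events.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
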