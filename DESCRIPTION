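Package: imufall
Title: IMU-Based Detection of Construction-Worker Falls, Stumbles and Comas
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for detecting common accidents of construction workers
    (falls from height, stumbles, and comas) from waist-worn inertial
    measurement unit streams sampled at 10 Hz.  Provides a labelled
    synthetic-scenario simulator emulating field conditions that provoke
    false alarms (uneven ground, gravel, stairs, slopes, motorcycle riding,
    resting), signal-vector-magnitude features, 2-second sliding-window
    segmentation, a calibrated hierarchical-threshold baseline detector,
    a gated-recurrent-unit (GRU) sequence classifier trained by
    backpropagation through time, and two-level evaluation per-time-unit
    confusion metrics and event-level sensitivity and false-alarm accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
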