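Package: foragekin
Title: Kinematic Segmentation and Analysis of Pick-and-Place Foraging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing markerless hand-tracking data from multi-target
    pick-and-place (foraging) experiments. Provides a synthetic-data generator for
    balanced trial schedules, minimum-jerk hand trajectories with planted condition
    effects and scene-image pairs; keypoint-track input/output with likelihood-based
    repair and physical calibration; Savitzky-Golay speed and acceleration profiles;
    objective-function segmentation of trials into reach and transport movements with
    count validation and participant-level quality control; kinematic dependent
    variables (durations, speeds, deceleration time, distance, movement onset, path
    ratio); difference-image activation maps with quadrant quantification; and a
    statistics layer with participant-level aggregation, variance-stabilising
    transforms and default-prior (Jeffreys-Zellner-Siow) Bayes-factor t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    signal,
    zoo,
    tibble,
    dplyr,
    rlang,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
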