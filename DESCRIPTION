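Package: reachmetrics
Title: Kinematic and sEMG Analysis of Robot-Supported Reaching Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse three-dimensional upper-limb
    reaching sessions recorded with a robotic haptic interface. Provides a
    synthetic session generator built on minimum-jerk submovements, readers
    and writers for trajectory, surface EMG and trial-event files, event-driven
    movement segmentation, velocity-profile kinematics including a
    velocity-peak smoothness count, Butterworth/notch EMG preprocessing with
    peak-latency extraction, and two-way repeated-measures ANOVA with
    Mauchly's sphericity check, Greenhouse-Geisser correction and
    Bonferroni-corrected post-hoc paired comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
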