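Package: somnacc
Title: Posture-Based Sleep Monitoring from Sternum and Thigh Accelerometry
Version: 0.1.0
Authors@R:
    person("somnacc", "maintainers", email = "somnacc@example.org",
           role = c("aut", "cre"))
Description: Classifies body posture (lying, sitting, standing/walking) and
    posture changes from four-channel accelerometer recordings (a triaxial
    sternum sensor plus a single-axis thigh sensor, 64 Hz) and derives
    objective indicators of sleep duration and sleep quality for a night:
    time supine, total sleep time, still-position latency, sleep efficiency
    based on turning, rises, and sleeping-posture statistics. Gravity is
    separated from dynamic movement by windowed medians and standard
    deviations; supine torso rotation is tracked as a circular angle and
    segmented with an adaptive angular-change rule. Includes a synthetic
    night and calibration-protocol simulator with analytic ground truth, a
    threshold calibration routine (10-fold cross-validation), plain-text
    readers/writers for recordings, segment tables and night summaries, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
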