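Package: stridekit
Title: Foot-Mounted IMU Gait Analysis and Frailty Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for foot-mounted inertial measurement unit
    (IMU) recordings of walking tests in older adults: sensor calibration
    (bias, misalignment, scaling, clock), Mahony complementary-filter
    orientation estimation, gyroscope-threshold gait-phase segmentation
    (still / movement / foot-flat zones and heel-strike, toe-strike,
    heel-off, toe-off events from sagittal pitch extrema), strapdown
    integration with zero-velocity-update (ZUPT) drift correction, and the
    per-stride spatio-temporal metrics (stride time, phase percentages,
    cadence, speed, stride length, path lengths, clearance) with
    median-based stride filtering and register-level aggregation. Also
    implements deterministic scoring of the companion clinical instruments
    (4-m gait speed, Fried frailty phenotype, Short Physical Performance
    Battery, Short FES-I, Timed Up and Go handling) and a synthetic
    foot-IMU gait simulator with full ground truth for end-to-end
    validation.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
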