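Package: posturewatch
Title: Posture Classification from Wearable Accelerometer and Magnetometer Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Calibrates per-pose trivariate Gaussian confidence regions from
    wearable accelerometer and magnetometer recordings, classifies posture by
    testing sensor readings against chi-squared density thresholds, fuses the
    two sensor verdicts (incorrect only when both sensors agree), scores
    monitoring sessions as the percentage of time spent in a correct posture,
    and validates back-angle estimates derived from the gravity direction.
    Includes a physics-based wearer/sensor simulator (gravity projection for
    the accelerometer; Earth field plus shoulder-mounted magnetic dipoles for
    the magnetometer) that generates calibration pose sets and labelled test
    scenarios, and a command-line interface covering the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
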