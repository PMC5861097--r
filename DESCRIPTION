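Package: pupilcurve
Title: Task-Evoked Pupillometry: Simulation, Preprocessing, Curve
    Statistics and Mixed-Effects Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for task-evoked pupillary response analysis:
    simulation of sample-level eye-tracking datasets with a known effect
    structure, blink detection and cubic-spline repair, Savitzky-Golay
    smoothing and decimation, pre-trial and resting baseline correction,
    extraction of pupil-response-curve statistics (peak dilation, peak
    time, dilation and contraction rates), event-locked aggregation of
    percent-change curves, and mixed-effects inference on how valence
    intensity, confidence, stimulus duration, response time and baseline
    pupil size shape the response. All user-facing functions take data
    frames and return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    generics,
    signal,
    lme4,
    glmmTMB,
    mgcv,
    emmeans,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
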