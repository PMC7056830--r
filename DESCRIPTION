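Package: tactomyo
Title: Tactile Myography Myocontrol: Ridge-Regression Intent Detection,
    ROI-Gradient Features, and Target Achievement Control Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for proportional, simultaneous myocontrol from
    high-density force myography (tactile myography). Implements the data
    model and causal Butterworth low-pass filtering for 288-taxel bracelet
    streams, two feature pipelines (raw filtered taxels and region-of-interest
    gradient plane-fit features), closed-form ridge-regression intent
    detection mapping features to graded activation levels, grip-strength
    biomechanics limits for feasible combined-action targets, a synthetic
    tactile-data simulator built on linear superposition of per-action
    muscle-bulge patterns (with sensor noise, compressive response,
    saturation, and drift), and a Target Achievement Control (TAC) test
    engine reporting success rate, time to complete task, time in target,
    and reachability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    MASS
Config/testthat/edition: 3
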