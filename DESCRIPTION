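Package: ovucycle
Title: Delay-Differential Modelling of the Human Menstrual Cycle and
    Optimal Contraceptive Dosing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A 13-state delay-differential-equation model of the
    pituitary-ovarian axis (LH, FSH, estradiol, progesterone, inhibin)
    with exogenous estrogen/progesterone inputs.  Provides simulation of
    the normal and anovulatory cycle, staged weighted least-squares
    calibration against daily hormone data, constant-dose anovulation
    scans and combination-therapy contour maps, and optimal-control
    minimisation of time-varying dosing schedules by control
    parameterization over piecewise-cubic nodes.  Includes a synthetic
    hormone-data generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    pracma,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
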