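Package: morphochron
Title: Model-Based Dating of Sequentially Initiated Plant Organs and
    Reconstruction of Age-Indexed Morphogenetic Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for recovering chronological time from static,
    destructive observations of growing plant organs. An ODE population
    model of sequential organ apparition is fitted to cross-sectional
    organ counts to estimate per-rank initiation times; Hill growth
    curves calibrated on static size measurements are inverted to date
    individual organs from their size; dated, landmarked 2D blade
    contours are combined by time-weighted averaging into continuous
    mean-shape trajectories, with blade-scale (aspect ratio, dissection
    index) and tooth-scale (width, height, aspect) morphometrics. A
    synthetic-data generator with known ground truth (initiation
    schedules, Hill parameters, parametric serrated contours) supports
    validation of the whole pipeline.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
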