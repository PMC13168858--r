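Package: ocufatigue
Title: Ocular Biometrics and Risk Modeling for Short-Term Visual Fatigue
Version: 0.1.0
Authors@R: person("OcuFatigue", "Developers", email = "ocufatigue@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing brief binocular eye-tracking recordings to
    monitor short-term visual fatigue (asthenopia). Provides a synthetic
    generator for per-frame ocular traces (eyelid aperture, pupil diameter,
    pupil centroid) and rendered eye frames with ground-truth masks;
    evaluation of instance-segmentation masks (Dice, IoU, Hungarian matching,
    COCO-style AP/AR); extraction of blink, fixation, PERCLOS, eye-movement
    and pupillometry metrics with windowed variability features; cohort
    statistics (Shapiro-Wilk gated paired tests, Mann-Whitney U, McNemar)
    with p-value feature filtering; leakage-aware machine-learning risk
    classifiers (decision tree, random forest, gradient boosting, RBF-SVM
    with PCA) trained with in-fold SMOTE balancing and stratified
    cross-validation; and a command-line interface that emits per-session
    risk reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    clue,
    quadprog,
    sp
Suggests:
    testthat (>= 3.0.0),
    png,
    withr
Config/testthat/edition: 3
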