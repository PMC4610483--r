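Package: spiralkin
Title: Spatiotemporal Analysis of Digital Spiral Drawings for Motor Symptom Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies upper-limb motor symptoms from timestamped spiral-tracing
    trajectories recorded on touch-screen devices. Computes kinematic series
    (speed, radius, radial and angular velocity) and a panel of spatiotemporal
    features including Approximate Entropy, Daubechies-10 wavelet detail-band
    statistics, local-extreme (delta-peak) summaries, drawing asymmetry, and
    Archimedean spiral fit errors with a differential-evolution search for the
    optimal spiral origin. Features are reduced with correlation-matrix PCA and
    classified as bradykinetic versus dyskinetic with stratified k-fold
    cross-validation; rater-agreement statistics (weighted kappa, mean pairwise
    correlations, Spearman matrices) are included, as is a synthetic spiral
    simulator that emulates healthy, bradykinetic, dyskinetic and tremor tracing
    signatures for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    nnet,
    randomForest,
    e1071,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
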