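Package: ecgduo
Title: Two-Way 12-Lead ECG Disease Classification from Digital Signals and Plot Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds standard 12-lead electrocardiogram (ECG) records
    (2.5 s of each of 12 leads plus a 10 s lead II rhythm strip) from raw
    digital recordings, renders them as ECG-paper images, simulates
    smartphone-camera acquisition (random perspective warp over a random
    table-texture background), and trains per-condition binary
    convolutional classifiers on either modality: a dual-branch temporal
    network for digital signals and a 2-D network for images. Ships a
    seeded synthetic 12-lead ECG generator covering nine rhythm and
    morphology classes (normal sinus, atrial fibrillation, first-degree
    AV block, left/right bundle branch block, premature atrial and
    ventricular contractions, ST depression and elevation) so the whole
    pipeline is testable end to end, an HDF5 dataset store with
    patient-disjoint splitting, and an evaluation suite (sensitivity,
    specificity, predictive values, accuracy, F1, ROC/AUC, a
    single-disease confusion matrix, and accuracy-versus-training-size
    analysis with sine-curve fitting).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    rhdf5,
    png,
    yaml,
    jsonlite,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
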