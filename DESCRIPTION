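Package: mvlesion
Title: Multi-View Attention-Guided Classification of Spinal Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for differentiating spinal lesion classes from tri-view
    (sagittal, axial, coronal) magnetic resonance volumes. Implements the
    DICOM patient-coordinate affine geometry used to transfer a sagittal
    lesion annotation onto the other two views, a multi-view convolutional
    classifier with log-sum-exp pooling and class-activation-map attention
    supervision, a handcrafted radiomics baseline (shape, first-order,
    gray-level co-occurrence and wavelet features with random-forest
    selection and gradient boosting), a stratified cross-validation
    harness with ROC/AUC reporting, and a synthetic tri-view phantom
    generator so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    randomForest,
    xgboost,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
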