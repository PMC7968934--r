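Package: chromocell
Title: Single-Cell Segmentation and Colorimetric Classification of
    Bright-Field Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Segments individual cells from color bright-field micrographs
    of dye-stained cultures by intersecting two independent foreground
    estimates (k-means pixel clustering in CIELAB and Otsu thresholding in
    grayscale) and splitting the conservative mask with marker-controlled
    watershed; extracts sixteen colorimetric intensity features per cell
    (total, mean, median and standard deviation of the red, green, blue
    and luminance channels); and classifies cell populations with PCA
    followed by five fixed-hyperparameter models under stratified 10-fold
    cross-validation, reporting accuracy, precision, recall, F1, confusion
    matrices, ROC/AUC and t-SNE maps. A synthetic scene generator with
    analytic ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    glmnet,
    ranger,
    e1071,
    stats,
    tools,
    utils,
    tiff,
    png,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    cluster,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
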