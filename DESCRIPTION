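Package: esoMorph
Title: Esophageal Wall Morphometry and Cancer Detection from Chest CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Tools for detecting esophageal cancer on non-contrast chest CT
    downstream of an esophagus segmentation mask. The pipeline removes
    intraluminal air to delineate the esophageal wall, measures per-cut-plane
    diameter and wall thickness with Euclidean distance transforms, extracts
    and straightens the organ centerline, divides the straightened esophagus
    into upper (5 cm), middle (10 cm), and lower (remainder) segments,
    computes per-segment summary features (means, variances, maxima of
    diameter and wall thickness), and classifies each segment with a decision
    tree, aggregating to a patient-level diagnosis. A synthetic
    esophagus-phantom generator provides CT volumes, masks and ground truth
    for testing and calibration, and a diagnostic-statistics suite implements
    confusion-matrix metrics, ROC AUC, DeLong's paired AUC test, the
    intraclass correlation coefficient, Dice overlap, Hausdorff distance and
    reader-study report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    EBImage,
    igraph,
    rpart,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
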