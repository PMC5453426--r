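Package: hepatch
Title: Patch-Based Multi-Scale CNN Classification of H&E Breast Histology Images
Version: 0.1.0
Authors@R:
    person("hepatch", "maintainers", email = "hepatch@example.org", role = c("aut", "cre"))
Description: A complete, self-contained pipeline for classifying hematoxylin
    and eosin (H&E) stained breast-histology images into normal tissue, benign
    lesion, in situ carcinoma and invasive carcinoma (plus the grouped
    carcinoma / non-carcinoma binary task). Implements optical-density H&E
    stain normalization with an SVD-derived stain plane and a 90%-coverage
    histogram stretch; overlapping-patch extraction with 8-fold dihedral
    augmentation; a declarative multi-scale convolutional network whose
    per-layer output shapes and effective receptive fields (in pixels and
    micrometres) are propagated and verifiable; seed-reproducible patch-wise
    training with categorical cross-entropy and an adaptive-learning-rate
    optimizer; patch-to-image probability fusion by majority vote, maximum
    probability or probability sum with malignancy-priority tie-breaking; an
    RBF-kernel SVM head on fully-connected-layer features; evaluation reports
    (accuracy, per-class sensitivity, subset pooling); and a seeded synthetic
    histology-image generator so every stage is testable without the original
    dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
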