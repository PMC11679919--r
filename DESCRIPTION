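Package: emotionatlas
Title: Emotion Atlas Construction and Group Analysis for Task and
    Resting-State fMRI
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds voxel-level positive and negative emotion atlases from
    block-design task fMRI by two-stage SVM-RFE feature selection
    (cross-validation-averaged squared-weight ranking at region level, then
    voxel level within characteristic regions) followed by correlation-based
    recruitment of external voxels, and applies the atlases to two-group
    resting-state cohorts via cost-sensitive RBF-SVM classification and
    voxelwise ALFF group statistics with FDR control and cluster reporting.
    Includes a seeded synthetic-data generator (parcellations, block-paradigm
    task runs, two-group resting cohorts with implanted band-limited effects)
    so the whole pipeline is testable end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    e1071,
    RNifti,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    kernlab,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: FunctionalGenomics, Classification, FeatureExtraction,
    StatisticalMethod
RoxygenNote: 7.3.3
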