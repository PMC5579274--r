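Package: radrisk
Title: Radiomic Feature Extraction and Imbalance-Adjusted Risk Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end radiomics for 3D PET/CT tumour imaging: isotropic
    resampling and gray-level quantization of regions of interest, the four
    classical 3D texture matrices (GLCM, GLRLM, GLSZM, NGTDM) built with
    merged 13-direction analysis and distance-aware diagonal handling, and a
    battery of 1615 named intensity, shape and texture features per imaging
    modality. Outcome models are built with imbalance-adjusted learning:
    balanced partition ensembles, 0.632+ bootstrap forward feature selection
    with bootstrap-averaged logistic coefficients, and partition-ensemble
    random forests combining radiomic and clinical variables. Evaluation
    covers ROC metrics, DeLong comparisons, Harrell's concordance index and
    Kaplan-Meier risk stratification. A synthetic-phantom and
    synthetic-cohort generator supports fully reproducible experiments
    without patient data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    survival,
    pROC,
    randomForest,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
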