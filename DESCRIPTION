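Package: petrad
Title: PET Radiomics Cross-Combination Modelling for Treatment Response and Survival
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end PET radiomics pipeline for response prediction and
    prognosis in aggressive lymphoma. Segments lesions on SUV-calibrated PET
    volumes with a 41%-of-SUVmax threshold, computes metabolic metrics
    (SUVmax, MTV, TLG) and a 110-feature IBSI-style radiomic catalogue
    (shape, first-order, GLCM, GLRLM, NGTDM, GLSZM), screens features with a
    7x7 selector-by-classifier cross-combination grid under cross-validation,
    builds a weighted radiomic score (RadScore) with Youden-index cutoffs,
    and evaluates logistic prediction models (ROC, calibration, decision
    curves, nomogram) and survival (Kaplan-Meier, log-rank, Cox). Includes
    synthetic PET phantom and patient cohort generators so the whole pipeline
    is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    RNifti,
    glmnet,
    ranger,
    xgboost,
    e1071,
    rpart,
    pROC,
    survival,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
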