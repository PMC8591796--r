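Package: dosiomics
Title: Dosiomics and DVH Modeling of Radiation Pneumonitis from Fractionated 3D Dose Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to predict radiation pneumonitis risk from 3D radiotherapy
    dose distributions. Provides voxel-wise conversion of per-fraction dose
    grids to equivalent dose in 2 Gy fractions (EQD2) under the
    linear-quadratic model, dose-volume histogram metrics (Vx, mean lung
    dose, gEUD) and a from-scratch dosiomic texture feature extractor (18
    first-order plus 75 GLCM/GLRLM/GLSZM/NGTDM/GLDM features) over a lung
    region of interest, Spearman redundancy filtering, repeated-holdout
    LASSO-logistic modeling with nested cross-validated tuning, and
    AUC-based comparison of DVH versus dosiomic feature groups with and
    without EQD2 correction. A synthetic fractionated-cohort generator with
    plantable dose-volume and texture effects supports end-to-end testing
    without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    glmnet,
    jsonlite,
    RNifti,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
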