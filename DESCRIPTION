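Package: scarDE
Title: Radiomic Detection of Myocardial Scar on Delayed-Enhancement Cardiac CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for estimating and classifying myocardial scar on
    delayed-enhancement cardiac CT using a reference scar segmentation from
    late gadolinium enhancement MRI. Implements three-step rigid mesh
    registration (major axis, right-ventricular insertion points, iterative
    closest point) for cross-modality scar-label transfer, short-axis
    reslicing with transmural scar masks, 93 two-dimensional radiomic
    features across six families (first order, GLCM, GLDM, GLSZM, GLRLM,
    NGTDM), combined-energy image synthesis, per-feature discrimination
    screening with patient-wise cross-validated ROC analysis, and
    per-AHA-segment scar classification with support vector machine,
    logistic regression and random forest models. Ships a synthetic
    left-ventricle phantom generator so the full pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    RNifti,
    e1071,
    ranger,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
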