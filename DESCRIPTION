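Package: lesionCADx
Title: Cross-Protocol Computer-Aided Diagnosis of Breast Lesions from DCE-MRI and DWI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for computer-aided discrimination of malignant
    versus benign breast lesions imaged with dynamic contrast-enhanced MRI and
    two-b-value diffusion-weighted MRI, under a train-on-one-protocol /
    test-on-another design (1.5 Tesla versus 3.0 Tesla). Lesions are segmented
    by fuzzy c-means clustering refined with a gradient-vector-flow snake, then
    characterized by 27 named features spanning morphology, gray-level
    co-occurrence (Haralick) texture, enhancement kinetics (early-phase
    enhancement and signal enhancement ratio) and the apparent diffusion
    coefficient. Per-feature diagnostics use best-cutoff selection and
    maximum-likelihood binormal ROC analysis; a compact diagnostic subset is
    selected by local-hyperplane RELIEF feature weighting; and cross-cohort
    classification scenarios are evaluated with SVM, k-nearest-neighbour and
    random-forest back-ends. A synthetic phantom cohort generator provides
    fully reproducible two-protocol test beds.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    RNifti,
    mgcv,
    e1071,
    class,
    randomForest,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
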