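Package: petrad
Title: Multi-Lesion FDG-PET Radiomics, Dissemination Features and Model Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of multi-lesion FDG-PET images in
    aggressive lymphoma: synthetic SUV phantom cohorts with a known outcome
    link, fixed-threshold lesion delineation (SUV >= 4.0, >= 3 mL) with
    programmatic mask editing and scan quality control, an IBSI-aligned
    radiomics engine (5 conventional PET, 22 morphology, 50 intensity and 408
    texture features over six grey-level matrix families), 18 patient-level
    lesion dissemination features, assembly of twelve lesion/feature-selection
    model variants, and a repeated stratified cross-validation harness with
    SMOTE oversampling, six feature-reduction methods, fold-wise DeLong AUC
    comparison with median p values, and random-forest feature importance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    igraph,
    purrr,
    ranger,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
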