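Package: dwicadx
Title: Model-Based Discrimination of Breast Lesions from Directional
    Diffusion-Weighted MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computer-aided discrimination of benign from malignant breast
    lesions using directional diffusion-weighted MRI. Builds directional and
    augmented apparent-diffusion-coefficient (ADC) maps, grows 3D lesion
    volume models by Jaccard-maximized region growing, splits hand-drawn
    regions of interest into lesion-core and peri-lesion sub-regions, derives
    the anisotropy-sensitive SDAC and the periphery ACMB features, combines
    them by cross-validated logistic regression, and evaluates discrimination
    with binormal ROC analysis. Includes inter-observer agreement analysis
    (Dice, Wilcoxon signed-rank, McNemar) and a synthetic dense-breast
    phantom generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    glmnet,
    jsonlite,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'dwicadx-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'adc.R'
    'agreement.R'
    'classify_roc.R'
    'core_io.R'
    'features.R'
    'lesion_model.R'
    'methods.R'
    'pipeline.R'
    'roi_prep.R'
    'synthetic.R'
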