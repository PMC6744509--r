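Package: voxelfate
Title: Voxel-Wise Tissue Outcome Prediction for Acute Ischemic Stroke
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for voxel-wise prediction of final tissue
    outcome in acute ischemic stroke from multi-parametric MRI. Generates
    seeded synthetic patient cohorts with known ischemic core, penumbra and
    follow-up lesion geometry; computes apparent diffusion coefficient maps,
    semi-automatic core segmentation, distance and atlas features; performs
    dynamic susceptibility contrast perfusion analysis via block-circulant
    singular value decomposition deconvolution (CBF, CBV, MTT, Tmax);
    assembles 12-feature voxel tables with contralateral normalization and
    stratified class balancing variants; trains random decision forest,
    generalized linear model and k-nearest-neighbor classifiers under
    leave-one-patient-out cross-validation; binarizes infarct likelihood maps
    at Dice-optimal thresholds with 3D morphological post-processing; and
    evaluates predictions (Dice, sensitivity, specificity, Matthews
    correlation, surface distances, volume difference) against ground truth,
    including a single-parameter thresholding baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    RNifti,
    ranger,
    class,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
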