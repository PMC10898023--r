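Package: oppscreen
Title: Opportunistic Osteoporosis Screening from Axial CT Slices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a quantitative-CT opportunistic
    osteoporosis screening pipeline on synthetic vertebral phantoms:
    encoder-decoder vertebral-body segmentation with channel-attention skip
    fusion, ROI-based bone mineral density measurement with three-class
    bone-mass labeling (normal / osteopenia / osteoporosis at the 120 and
    80 mg/cm3 thresholds), a residual-network bone-mass classifier fed by
    L1+L2 channel-fused or L1-only vertebral images, and the full evaluation
    toolbox (Dice similarity, one-vs-rest ROC/AUC with DeLong confidence
    intervals and paired DeLong tests, sensitivity/specificity/predictive
    values, stratified ratio splitting, and contingency/summary-statistics
    tests). Networks are trained by a compact reverse-mode tape engine over
    compiled convolution kernels, so the whole pipeline runs on a single CPU
    against a built-in phantom generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    png,
    RNifti,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
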