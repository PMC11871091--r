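Package: hipseg
Title: Musculoskeletal Tissue Segmentation and Quantification for Proximal Hip CT
Version: 0.1.0
Authors@R:
    person("hipseg", "developers", email = "hipseg@example.org", role = c("aut", "cre"))
Description: Toolkit for segmenting and quantifying seven musculoskeletal tissues
    (cortical bone, trabecular bone, haematopoietic bone marrow, marrow adipose
    tissue, muscle, intermuscular adipose tissue and subcutaneous adipose tissue)
    in proximal-hip quantitative CT. Provides a synthetic hip-phantom generator
    with known ground truth and calibration rods, a Hounsfield-unit threshold
    reference-segmentation protocol, a Dense U-Net semantic segmentation model
    implemented natively (training and inference on CPU), segmentation metrics
    (Dice, average symmetric surface distance, sensitivity, specificity) with
    k-fold cross-validation and cross-domain robustness evaluation, and
    per-tissue quantification (area, volume, average HU, marrow fractions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
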