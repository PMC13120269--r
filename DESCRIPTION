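Package: shelladc
Title: Multilayered Peritumoral Shell ADC Analysis for Breast MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the tumor microenvironment on apparent diffusion
    coefficient (ADC) maps using concentric peritumoral shells grown from a
    tumor segmentation by a Euclidean distance transform. Provides NIfTI
    volume and mask handling, isotropic resampling, one-voxel boundary
    erosion, shell construction with exclusion masks, contralateral
    reference mirroring, per-patient normalized ADC (rADC) and
    intratumoral-to-peritumoral ratio metrics, nonparametric cohort
    statistics, ROC analysis with DeLong inference, Youden and
    fixed-sensitivity/specificity operating points, bootstrap optimism
    correction and repeated cross-validation, logistic models, intraclass
    correlation, and synthetic phantom and cohort generators for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
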