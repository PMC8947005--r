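Package: mlshift
Title: Automatic Midline-Shift Measurement from Head CT by Keypoint Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automatic measurement of brain midline shift (MLS) on axial
    head CT. Implements the keypoint-based MLS geometry (distance between the
    falx midline midpoint and the septum pellucidum midpoint, in mm), CT
    preprocessing (triple Hounsfield windowing, adjacent-slice stacking,
    bilinear resize to 512x512), a configurable two-stage keypoint detector
    (region proposals plus classification, box-regression and heatmap keypoint
    heads) trainable at desk scale, a synthetic head-phantom generator with
    exact ground truth, and the cohort evaluation protocol (MAE, ICC(2,1),
    threshold sensitivity/specificity, Pearson correlation). DICOM series and
    NIfTI volumes are supported as input.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    EBImage,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
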