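Package: segmargin
Title: Segmentation Accuracy and Safety-Margin Analysis for 3D Tumor Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how well candidate tumor segmentations on a
    common voxel grid agree with a ground-truth volume, and what isotropic
    safety margin is needed to cover the truth entirely. Implements overlap
    coefficients (Dice, Jaccard), surface distances (Hausdorff distance,
    mean distance to agreement), missed-volume fractions, millimetre contour
    expansion with minimum-coverage-margin search, ellipsoid-formula volume
    estimation, a radial gradient-based PET lesion segmenter, shape-based
    interslice interpolation of sparse contour stacks, and a synthetic
    tumor/reader/PET cohort generator so the full analysis pipeline can be
    exercised without patient data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
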