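Package: tbmpipe
Title: Tensor-Based Morphometry for Small-Animal Structural MRI
Version: 0.1.0
Authors@R: person("TBM", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale tensor-based morphometry (TBM) pipeline for
    three-dimensional structural MRI of the mouse brain. Provides NIfTI-1
    input/output and image geometry handling, a seeded synthetic phantom
    cohort generator emulating paired in vivo / ex vivo scans of wild-type
    and atrophic transgenic groups, intensity non-uniformity correction and
    piecewise-linear intensity standardization, multi-atlas mask fusion,
    rigid/affine and B-spline free-form non-rigid registration driven by
    normalized cross-correlation and normalized mutual information, the
    multi-iteration group-wise registration loop, log-Jacobian determinant
    maps, mean positional distance maps, voxelwise t-statistics with false
    discovery rate control, Cohen's d effect-size and per-voxel sample-size
    maps, and ROI-based SNR/CNR/total-brain-volume quality metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
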