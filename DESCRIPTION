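Package: qcmatch
Title: Propensity-Score Matching on MRI Quality Metrics for Scan Quality Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality control of structural MRI group studies by propensity-score
    matching on automated image-quality metrics (overall image quality rating,
    mean surface Euler number, topological defect size). Provides logistic
    propensity models, exact 1:1 optimal matching with caliper/exact/tiered
    variants, standardized-mean-difference balance diagnostics with Love-plot
    export, three quality-control protocols (full inclusion, threshold
    exclusion, matching), empirical-Bayes location/scale site harmonization,
    and voxel-based-morphometry group inference with Gaussian smoothing,
    per-voxel general linear models, permutation maxT familywise-error
    correction and cluster tables. Includes a synthetic motion-confounded
    cohort generator so the full pipeline can be exercised and validated
    without external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    sva,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
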