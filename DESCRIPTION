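Package: soalbp
Title: Scale- and Orientation-Adaptive Local Binary Patterns for Texture Classification
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Scale- and rotation-invariant texture features based on Local
    Binary Patterns (LBP). The global scale of an image is estimated from the
    distribution of scale-normalized Laplacian responses in a Gaussian
    scale-space, and a global orientation is estimated from multi-scale
    second-moment matrices. LBP neighborhoods are adapted to the estimated
    scale via per-class trained base scales (intrinsic-scale adaption), with
    Gaussian sampling supports sized by an integrated-Gaussian kernel, and
    aligned to the estimated orientation at the extraction level. Features
    across several base radii are combined into multi-resolution
    meta-descriptors compared by a histogram-intersection distance with
    validity-based feature-subset selection. Includes a k-nearest-neighbor
    evaluation harness with scale-constrained cross-validation and a
    synthetic-texture generator with controllable dominant scale and
    orientation for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    Rcpp,
    minpack.lm,
    jsonlite,
    png,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Software, Classification, FeatureExtraction, Visualization
RoxygenNote: 7.3.3
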