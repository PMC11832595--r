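Package: slicereg
Title: Rigid 2D Slice-to-3D Volume Ultrasound Registration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rigid registration of 2D ultrasound frames to a 3D ultrasound
    volume for organ-motion correction. Provides a differentiable volume
    slicing (spatial transformer) module with trilinear resampling and
    analytic pose gradients, a continuous 6D rotation representation with
    Gram-Schmidt orthogonalization, a masked-intersection local normalized
    cross-correlation (LNCC) similarity metric, a convolutional pose
    regression network with dot-product 2D/3D feature fusion, an iterative
    LNCC refinement stage and a global-NCC baseline registrar, a temporal
    correction workflow for frame sequences, a synthetic speckle-phantom
    generator with ground-truth poses, and pose-error/TRE/ECDF evaluation
    utilities.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
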