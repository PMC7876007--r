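Package: oticfit
Title: Template-Based Cochlear Morphometry from CT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits a template surface of the otic capsule to CT volumes by
    landmark initialization, similarity-transform iterative closest point
    registration, and regularized nonrigid refinement using either a locally
    affine deformation or a statistical shape model.  Computes clinically
    relevant cochlear measurements on the fitted surface: reach, outer-wall
    duct length, and the non-planarity of the basal turn relative to its
    best-fit plane.  Includes a synthetic cochlea phantom generator with
    analytic ground truth and a pseudo-clinical CT degradation simulator
    (sinogram-domain Gaussian noise with filtered backprojection) for
    end-to-end validation by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    grDevices,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
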