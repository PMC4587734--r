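Package: iterFBP
Title: Iterative Filtered Back-Projection for Parallel-Beam CT
Version: 0.99.0
Authors@R:
    person("Mara", "Vogel", email = "mara.vogel@posteo.net", role = c("aut", "cre"))
Description: Parallel-beam computed-tomography reconstruction by classic
    discrete filtered back-projection (FBP) together with an iterative
    correction scheme that reprojects the reconstruction, filters the
    reprojection residual with a short symmetric deconvolution filter
    designed against the spatial ramp kernel, and back-projects the
    filtered residual into an image correction.  Includes a Shepp-Logan
    phantom generator, a pixel-driven sub-pixel-splitting forward
    projector with its exact adjoint, SIRT/SART/MAP-EM reference
    reconstructors, image-quality metrics (MSE, universal quality index,
    mutual information, reprojection residual statistics), flat-/dark-field
    log normalisation for raw scans, and TIFF/CSV input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tiff,
    png,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
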