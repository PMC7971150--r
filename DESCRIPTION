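Package: hexsource
Title: EEG Source Localization of Epileptic Spikes with Hexahedral FEM Head
    Models, sLORETA and Multiple Sparse Priors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A complete electrical source imaging stack for averaged
    interictal spike EEG. Builds hexahedral finite-element volume-conductor
    models directly from labelled voxel segmentations (one trilinear cube
    element per voxel), computes lead fields through the reciprocity
    principle, and inverts scalp topographies with standardized
    low-resolution electromagnetic tomography (sLORETA) and a multiple
    sparse priors (MSP) restricted-maximum-likelihood solver. Candidate
    source configurations are ranked by the normalized relative difference
    measure between measured and reconstructed scalp fields, and solutions
    are scored against a volume of interest with localization-error,
    spatial-dispersion and focality metrics. Includes analytic multilayer
    sphere oracles and a sphere-phantom generator so every stage can be
    validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    igraph,
    RNifti,
    signal,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
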