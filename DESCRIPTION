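Package: ringtomo
Title: Tomographic Reconstruction with Built-In Ring Artifact Correction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Iterative parallel-beam tomographic reconstruction in which
    ring artifact correction is part of the optimization itself. The
    sinogram is modelled as the sum of a genuine component (the projection
    of the slice) and an angle-constant stripe component penalized in L1;
    both are estimated jointly by preconditioned FISTA under Total
    Variation or learned-dictionary sparsity priors. Includes a Joseph
    linear-interpolation projector with exact adjoint, ramp-filter
    preconditioning, filtered back-projection, a Chambolle-type TV
    proximal solver, K-SVD dictionary learning with orthogonal matching
    pursuit, a wavelet-Fourier sinogram destriping baseline, synthetic
    phantom and stripe-corruption generators, and TIFF/text input-output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tiff,
    withr,
    yaml,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
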