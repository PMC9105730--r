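Package: dualwave
Title: Dual-Domain Multi-Level Wavelet Networks for Sparse-View CT Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for sparse-view computed-tomography reconstruction built
    around a hybrid-domain deep model: a radon-domain sinogram-completion
    network and an image-domain restoration network, joined by a
    differentiable filtered back-projection bridge and trained end-to-end.
    Both networks are multi-level wavelet CNNs in which an unnormalized Haar
    transform replaces pooling, so downsampling is lossless and invertible.
    Includes a parallel-beam projector and its exact adjoint, filtered
    back-projection, angular subsampling and sinogram interpolation,
    Shepp-Logan and random-ellipse phantom generators, classical SART and
    SART-TV baselines, PSNR/SSIM metrics, and a command-line workflow for
    simulate/train/reconstruct/evaluate experiments on synthetic phantoms.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
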