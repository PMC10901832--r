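Package: patrecon
Title: Learned Fourier-Domain Reconstruction for Planar Photoacoustic Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for three-dimensional limited-view photoacoustic tomography
    with a planar sensor. Provides a fast, differentiable FFT-based
    reconstruction operator built on the planar dispersion relation, k-space
    pseudospectral acoustic forward solvers for homogeneous and heterogeneous
    speed of sound, a time-reversal baseline, procedural vessel-mimicking
    phantoms and layered sound-speed maps, complex-valued convolutional
    network building blocks with hand-written reverse-mode gradients, a
    k-space model-correction network, an image-space post-processing U-Net,
    joint end-to-end training, and PSNR/SSIM evaluation harnesses for
    sound-speed-sweep experiments.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    yaml,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
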