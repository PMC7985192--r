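Package: vrefocus
Title: Virtual Refocusing of Sparse Wide-Field Fluorescence Z-Scans with a
    Convolutional Recurrent Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs a fluorescence sample volume at arbitrary axial
    planes from a few sparsely acquired 2D wide-field scans.  Each input
    image is paired with a digital propagation matrix (DPM), a constant
    matrix encoding the signed axial distance to the desired output plane,
    and a convolutional-recurrent (GRU) encoder-decoder network fuses the
    sequence into a single refocused image.  Includes a synthetic wide-field
    defocus simulator (bead and filament phantoms), the normalization and
    tiling preprocessing pipeline, composite BerHu + multi-scale SSIM +
    least-squares adversarial training implemented in pure R, volume
    inference with an adaptive plane-count stopping rule, and a full
    evaluation harness (NRMSE, PSNR, ROI-RMSE, bead FWHM distributions and
    their KL divergence, axial-permutation statistics, and DPM noise
    stability sweeps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    EBImage,
    minpack.lm
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
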