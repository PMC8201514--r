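Package: sctgan
Title: Synthetic CT Generation from Megavoltage CBCT with a Cycle-Consistent Adversarial Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Translates megavoltage cone-beam CT (MV-CBCT) volumes into
    synthetic CT (sCT) volumes with diagnostic-quality Hounsfield units using a
    cycle-consistent adversarial network (CycleGAN) trained on unpaired slices.
    Provides the full pipeline: DICOM/NIfTI volume I/O, resampling, Otsu body
    masking and intensity scaling; a residual U-Net generator and PatchGAN
    discriminator with a four-term generator loss (cycle, idempotence,
    adversarial, gradient) trained with Adam; inference back to Hounsfield
    units; image-quality metrics (MAE, PSNR, NCC, SSIM) and the Dice
    similarity coefficient; and a seeded pelvic-phantom simulator with a
    CBCT-degradation model so the whole system is trainable and testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    EBImage,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    generics,
    rlang,
    jsonlite,
    yaml,
    optparse,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
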