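Package: adcgan
Title: GAN-Based Synthesis of Zoomed-FOV-Quality ADC Maps from Single-b-Value Prostate DWI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A supervised image-to-image translation framework for prostate diffusion
    MRI: a least-squares GAN with a multi-level verification (perceptual) loss that
    synthesizes zoomed-field-of-view-quality apparent diffusion coefficient (ADC) maps
    from single-b-value full-field-of-view diffusion-weighted images. Includes a seeded
    zonal prostate phantom simulator with Rician noise and phase-encode distortion,
    mono-exponential ADC fitting, preprocessing (resampling, intensity-based affine
    alignment, cropping, rescaling, normalization), full-reference image-quality
    metrics (RMSE, PSNR, SSIM, FSIM) and prostate diameter distortion, and the
    agreement/diagnostic statistics used to evaluate ADC maps (ICC with F-based
    confidence intervals, ROC/AUC, DeLong comparison of correlated AUCs, rank tests),
    orchestrated by an end-to-end reproducible study runner.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
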