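Package: PADenoise
Title: Platform-Flexible Single-Pulse Photoacoustic Image Denoising
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conditional generative adversarial denoising of single-pulse
    photoacoustic (PA) B-scans, built around a Pix2Pix-style generator trained
    with a combined adversarial + Huber + structural-similarity objective and a
    PatchGAN discriminator. Includes the classical baselines (Savitzky-Golay,
    pixel-wise adaptive Wiener, pluggable BM3D), no-reference image-quality
    metrics (SNR, CNR, GCNR), noise-profile characterization via FFT power
    spectra, four synthetic noise injectors (Gaussian, Poisson, salt-and-pepper,
    speckle), and a synthetic phantom / frame-averaging / raster-scan
    photobleaching simulator so that training, evaluation and the
    photobleaching trade-off study all run at desk scale with no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
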