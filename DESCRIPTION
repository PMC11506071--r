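Package: larynet
Title: Adversarial U-Net Segmentation of Color-Coded Laryngoscopy Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pixel-level semantic segmentation of laryngeal endoscopy images with a
    modified attention U-Net trained as a weight-clipped Wasserstein-style GAN whose
    encoder doubles as the discriminator. The package provides the seven-color lesion
    codec used to paint and decode polygon ground-truth masks, a synthetic
    laryngoscopy-like scene generator for fully self-contained training and testing,
    the adversarial training loop (blended MSE/SSIM reconstruction, label-smoothed
    auxiliary classification, latent-consistency and open-set validity objectives,
    discriminator weight clipping), and the complete pixel-level evaluation stack:
    per-class hue-band confusion matrices, accuracy, precision, recall, F1, pixel and
    bounding-box IoU, an AUC approximation, Gram-matrix encoder error, polygon
    extraction, and CSV/JPG/PNG reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    png,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
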