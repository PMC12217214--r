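Package: vistain
Title: Virtual Histological Staining of Label-Free Autofluorescence Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for computational ("virtual") histological staining of
    unlabeled tissue sections imaged by multi-channel autofluorescence
    microscopy. Builds pixel-registered training pairs from autofluorescence
    and histochemically stained bright-field whole-slide images through a
    three-step registration cascade (rigid cross-correlation, multimodal
    affine via mutual information, iterative elastic pyramid block matching
    with a rough virtual stainer in the loop), filters pairs by PSNR/SSIM
    quality control, trains a structurally conditioned generative adversarial
    network (5-level U-Net generator, convolutional discriminator, L1 +
    total-variation + adversarial losses), harmonizes stain color styles
    across laboratories with a cycle-consistent translator, and renders
    virtually stained whole-slide images by tiled inference with feathered
    stitching. A synthetic tissue-phantom generator with a Beer-Lambert stain
    forward model provides fully known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    tiff,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
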