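Package: vstain
Title: Label-Free Virtual HER2 Immunohistochemistry by Conditional
    Adversarial Image Translation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for virtual HER2 immunohistochemical (IHC) staining of
    label-free breast tissue imaged by multi-channel autofluorescence
    microscopy. Implements the full workflow: elastic cross-modality
    registration of autofluorescence and brightfield whole-slide images
    (feature matching, tile pairing, style-bridge assisted pyramid block
    matching), a conditional generative adversarial network with an
    attention-gated U-Net generator and a residual CNN discriminator
    trained with a composite smooth-L1 / SSIM / adversarial loss,
    tile-wise inference with feathered stitching, feature-based HER2
    stain quantification (hematoxylin/DAB colour deconvolution, nucleus
    statistics, membrane characteristic curves and connectedness), and
    the blinded-study statistics used to compare virtual against
    chemically stained slides. A seeded synthetic tissue simulator
    renders paired autofluorescence/IHC tiles with grade-dependent
    membranous staining so the whole pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
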