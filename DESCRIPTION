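Package: nucadapt
Title: Adversarial Domain Adaptation for Nuclei Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Unsupervised and semi-supervised adversarial domain adaptation
    for binary nuclei segmentation in histopathology image patches. Provides
    a U-Net segmentation network, a prediction-to-image reconstruction
    network, patch discriminators in output space and image space, the full
    set of training losses (dice + entropy-minimization segmentation loss,
    prediction and image adversarial losses, reconstruction loss,
    target-translated source supervision, class-centroid clustering loss),
    alternating GAN-style training loops for the UDA and SSDA objectives, a
    two-domain synthetic nuclei benchmark generator, segmentation metrics
    (IoU, Dice, Hausdorff distance), and a command-line interface. All
    network computation runs on CPU via a small built-in convolution engine.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
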