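Package: fundusnet
Title: Glaucoma Classification from Fundus Photographs with Hybrid
    Attention Normalization-Free Residual Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Binary glaucoma screening from retinal fundus photographs with
    normalization-free residual network (NF-ResNet) feature extractors, a
    hybrid channel-plus-spatial attention block inserted before a global
    average pooling classification head, and Grad-CAM++ heatmap explanations.
    Includes the full training recipe (Adam, linear warm-up plus cosine decay,
    random crop/flip/colour-jitter augmentation), patient-level and
    multi-dataset five-fold cross-validation split protocols, a binary
    classification metrics suite (accuracy, sensitivity, specificity, F1,
    Cohen's kappa, ROC/AUC), and a seeded synthetic fundus-image generator in
    which the cup-to-disc ratio determines the class label, so the whole
    pipeline is testable at desk scale without external datasets. The
    convolutional compute core (convolution, pooling, weight standardization,
    backpropagation, Adam) is implemented in C++ via RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
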