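Package: fmcnet
Title: Feature Multi-Connection Convolutional Networks for Lymph Node
    Metastasis Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and trains small AlexNet-style convolutional networks in
    which the outputs of the deeper convolutional layers (conv3-conv5) are
    routed forward and concatenated into a merged layer before classification
    (a feature multi-connection, FMC, wiring), without changing the depth or
    the per-layer widths of the backbone.  Provides the layer primitives
    (local response normalization, channel concatenation, Lp feature
    reduction), a bespoke momentum-SGD trainer with layer freezing for
    transfer learning, a diagnostic evaluation panel (sensitivity,
    specificity, PPV, NPV, accuracy, ROC/AUC), merged-layer width search and
    connection-pattern ablation harnesses, class-activation heat maps, and a
    synthetic generator of lymph-node-like grayscale patches whose positive
    class differs by border irregularity, intensity heterogeneity, and
    roundness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
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
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
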