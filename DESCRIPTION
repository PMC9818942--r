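Package: cwriig
Title: Correlated-Weighted Multiresolution RiIG Parametric Imaging for
    Breast Ultrasound Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for speckle-statistics-based classification of breast
    ultrasound B-mode images. Implements contourlet and curvelet
    multiresolution decompositions with perfect reconstruction, Rician
    inverse Gaussian (RiIG), Nakagami and normal inverse Gaussian (NIG)
    envelope models with samplers and maximum-likelihood fitters,
    sliding-window parametric (delta, m, alpha) imaging of transform
    sub-bands, correlated and multiplicative sub-band weighting, a compact
    convolutional network with a combined softmax-plus-sigmoid output
    activation operating on six-channel 224x224 sub-band stacks, classical
    classifiers on pooled network features, a seeded synthetic-speckle
    generator for fully developed speckle with elliptical lesions, and a
    command-line pipeline tying the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    png,
    yaml,
    jsonlite,
    e1071,
    class,
    randomForest,
    EBImage
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
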