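Package: dermofuse
Title: Dermoscopy Lesion Classification by Hybrid and Deep Feature Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A melanoma screening pipeline for dermoscopy images: modified
    anisotropic diffusion despeckling with a residual-Gaussianity (excess
    kurtosis) stopping rule, fast-bounding-box lesion localization from
    intensity mass profiles, hand-crafted HOG/LBP/SURF descriptors fused
    with features from a VGG19-topology convolutional backbone,
    entropy-based selection of the fused vector, and classifier heads with
    confusion-matrix evaluation under stratified cross-validation. Includes
    a seeded synthetic dermoscopy generator with ground-truth masks so the
    full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    glmnet,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    nnet,
    rpart,
    randomForest,
    e1071,
    class
Config/testthat/edition: 3
RoxygenNote: 7.3.3
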