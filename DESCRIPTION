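Package: noduleseg
Title: Lung Nodule Segmentation with Cuckoo-Search Thresholding and an
    Encoder-Decoder Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for segmenting lung nodules in 2-D CT slices and
    validating segmentation pipelines on synthetic phantoms. Provides CT
    preprocessing (min-max normalization, bilinear resizing, edge
    enhancement, weighted histogram equalization), multilevel Otsu
    thresholding optimized by a cuckoo search metaheuristic with Levy
    flights, local binary pattern texture features with sign-unit and
    penalized logistic classifiers, a SegNet-style convolutional
    encoder-decoder with max-pooling index unpooling trained by
    backpropagation, evaluation metrics (volume error, Dice, Jaccard,
    accuracy, F1, RMSE) with a k-fold cross-validation harness, and a
    deterministic generator of CT-like lung phantoms with ground-truth
    nodule masks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
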