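Package: emrcnn
Title: Convolutional Neural Network Diagnosis from Electronic Medical Record Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains and evaluates a multi-kernel convolutional neural network
    that reads free-text electronic medical records (chief complaint, history
    of present illness, physical examination) and predicts a diagnosis among a
    fixed set of diseases. Implements the full pipeline as a tidyverse-style
    toolkit: text tokenization with a pluggable segmenter, frequency-filtered
    vocabulary construction, fixed-length integer encoding with zero padding,
    an embedding layer, convolution kernels of several heights with ReLU and
    global max pooling, a dense softmax classifier, squared-error training
    with L2 regularization, dropout and momentum stochastic gradient descent
    (all gradients computed analytically in-package), one-vs-rest confusion
    metrics, and feature-space analysis via t-SNE projection and silhouette
    separation scores. A seeded synthetic EMR corpus generator makes every
    stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rtsne,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
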