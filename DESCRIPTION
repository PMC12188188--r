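Package: camformer
Title: Residual Convolutional Networks for Promoter-Driven Expression Prediction
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts gene expression from short promoter sequences with a
    family of residual one-dimensional convolutional networks, as used for
    gigantic parallel reporter assay (GPRA) data. Provides the full analysis
    stack around the model: reading and standardizing promoter-expression
    tables, five one-hot sequence encodings, a pure-R training engine with
    L1/MSE/Huber losses, AdamW and Lion optimizers, learning-rate schedulers
    and early stopping on validation r+rho, seed ensembles and subsampling
    curves, the competition-style weighted evaluation metrics, explainability
    via in-silico saturation mutagenesis and Grad-CAM, position weight matrix
    scanning and motif enrichment with co-occurrence expression analysis, and
    a synthetic GPRA library simulator with planted regulatory logic and a
    binned flow-sorting readout model for ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
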