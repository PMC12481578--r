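Package: serskit
Title: Deep Learning Quantification and Context Explainability for SERS Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-stage analysis framework for surface-enhanced Raman
    spectroscopy (SERS) bioquantification: spectral preprocessing (asymmetric
    least-squares baseline correction, min-max normalization, Savitzky-Golay
    derivatives) with a denoising autoencoder trained to remove biological
    background; neural quantification models (1-D convolutional networks with
    three-parameter-logistic, multiscale and local region-scaling layers, and a
    1-D vision transformer) with an ensemble training protocol; and a
    context-explainability stage that clusters per-instance LIME explanations
    in the latent space of a variational autoencoder and matches each context
    to analyte reference spectra by weighted cosine similarity. Includes a
    synthetic SERS mixture generator emulating a confounded neurotransmitter
    study design, classical chemometric benchmarks, and perturbation
    robustness testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    mixOmics,
    randomForest,
    e1071,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
LinkingTo:
    Rcpp
Config/testthat/edition: 3
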