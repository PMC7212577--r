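Package: sgfa
Title: Sparse Bayesian Group Factor Analysis for Multi-Group, Multi-View Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a sparse Bayesian group factor analysis model to data sets
    that are structured into multiple feature views (data modalities) and
    multiple sample groups, with arbitrary missing values. Latent factors are
    regularized by a two-level prior: automatic relevance determination
    precisions acting per (factor, view) on the weights and per (factor,
    group) on the factors, combined with spike-and-slab sparsity. Inference
    is by mean-field variational Bayes, with an optional stochastic
    (mini-batch, natural-gradient) mode for large sample sizes. Bernoulli and
    Poisson observations are handled through local variational bounds.
    Downstream tools cover variance decomposition per factor, group and view,
    weight inspection, gene set enrichment of factor weights, reconstruction
    and imputation, a generative simulator for validation, and a versioned
    model container.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
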