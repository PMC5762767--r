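Package: sdamll
Title: Stacked Denoising Autoencoder Multi-Label Learning for Gene-Pathway Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Multi-label annotation of genes to pathways from sparse
    term-frequency features. Implements greedy layer-wise pretraining of
    stacked denoising autoencoders with tied weights and masking corruption,
    a multi-label feed-forward network trained online with the pairwise
    exponential ranking error (BP-MLL), their composition (SdaMLL), the
    ranking-based evaluation metrics coverage, ranking loss and average
    precision, k-nearest-neighbour and decision-tree baselines, a seeded
    k-fold cross-validation comparison harness with permutation-null
    significance, a synthetic term-frequency data generator, and a
    command-line interface over MatrixMarket/TSV inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    rpart,
    withr,
    methods,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
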