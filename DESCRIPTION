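Package: mldx
Title: Multilabel Diagnosis Classification for Sectioned Clinical Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for treating admitting diagnosis as a
    multilabel classification problem over sectioned first-course clinical
    records. Provides a seeded synthetic corpus generator with planted
    topic-label structure, record cleaning and label-space standardization
    by semantic similarity with frequency-based reduction, latent Dirichlet
    allocation by collapsed Gibbs sampling and skip-gram document embeddings
    as feature extractors, four multilabel classifiers (a pairwise-ranking
    neural network, multilabel k-nearest neighbors, random k-labelsets, and
    classifier chains), the five ranking-based multilabel evaluation
    measures, and cross-validated experiment runners.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    nnet,
    jsonlite,
    glmnet,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
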