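Package: lbpnotes
Title: Identifying Acute Low Back Pain Episodes in Free-Text Clinical Notes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for phenotyping acute low back pain (LBP) episodes from
    free-text primary-care notes. Implements a full comparison framework:
    keyword search with NegEx-style negation filtering, latent Dirichlet
    allocation topic scoring, TF-IDF n-gram LASSO logistic regression (with
    an optional curated n-gram lexicon), and a multi-kernel one-dimensional
    convolutional text classifier with skip-gram pretrained embeddings and
    log-odds n-gram attribution. Includes the evaluation protocol (10-fold
    cross-validation with per-fold threshold tuning, ICD-10 silver-label
    training, annotation subsampling) and a seeded synthetic clinical-note
    generator for end-to-end testing without protected health information.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
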