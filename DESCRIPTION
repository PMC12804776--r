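Package: hetnetDR
Title: Heterogeneous Network Methods for Drug-Disease Association Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and evaluation of heterogeneous drug-disease
    networks for computational drug repurposing. Builds the standard
    adjacency representations from drug-drug similarity, disease-disease
    similarity and binary drug-disease association matrices; implements
    non-negative matrix factorization with Lee-Seung multiplicative
    updates and SVD-based rank selection, a permutation-null variant
    (NMF-PDR) combining rank-sum statistics by Stouffer's method, bounded
    nuclear-norm matrix completion (BNNR) solved by ADMM, and overlap
    matrix completion (OMC) on one-sided stacked networks with k-nearest
    neighbour imputation. Provides Gaussian interaction profile kernel
    similarity, a planted-structure synthetic network generator, and a
    disease-centric stratified cross-validation harness with ranked
    AUC/AUPR metrics, including the balanced-subsample comparator that
    illustrates AUPR inflation on sparse networks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
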