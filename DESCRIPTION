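Package: m5usite
Title: Multi-View Sequence Features and SVM Prediction of RNA 5-Methyluridine Sites
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Toolkit for identifying RNA 5-methyluridine (m5U) modification
    sites from fixed-length sequence windows centered on a candidate uridine.
    Implements four physicochemical feature encoders (Kmer, ENAC, CKSNAP,
    PseDNC), skip-gram k-mer embeddings with mean pooling, two-step feature
    optimization (importance ranking plus accuracy-based incremental feature
    selection), support vector machine classification with grid search and
    stratified tenfold cross-validation, exact and sampled Shapley-value model
    interpretation, and position-wise nucleotide enrichment analysis, together
    with a synthetic window generator for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics,
    xgboost
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
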