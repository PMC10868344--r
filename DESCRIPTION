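Package: ppibench
Title: Benchmarking Toolkit for In Silico Protein-Protein Interaction
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building and auditing benchmarks of
    protein-protein interaction (PPI) prediction models. Provides
    curation of positive interactions from evidence tables, uniform and
    degree-balanced negative sampling, train/test splits with controlled
    protein-level overlap (T1 at 50% positives, T2 at realistic 1%
    prevalence), functional-genomics similarity features, reference
    baseline classifiers, evaluation stratified by protein-level overlap
    and network topology (hubs versus lone proteins), a DeLong test for
    correlated ROC curves, and carbon-footprint accounting for training
    runs. A synthetic interactome generator with scale-free topology and
    planted annotation/sequence signal makes every stage testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    Biostrings,
    e1071,
    ranger,
    xgboost,
    glmnet
Suggests:
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
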