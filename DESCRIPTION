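Package: circnea
Title: CircRNA-Disease Association Prediction via Attributed Network
    Embedding and a Dynamic Convolutional Autoencoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts circular RNA (circRNA)-disease associations from a
    bipartite association matrix, a disease ontology DAG and circRNA
    expression profiles. Builds four biometric similarity families
    (DAG-based disease semantic similarity, Gaussian interaction profile
    kernels, Spearman expression-profile similarity, Jaccard similarity),
    fuses them into per-pair feature vectors, extracts low-dimensional
    representations with an ADMM-based attributed network embedding and a
    dynamic convolutional autoencoder, and scores candidate pairs with a
    random-forest classifier under stratified cross-validation. Includes
    seeded synthetic-data generators with planted association blocks so
    the whole pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    randomForest,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
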