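Package: spmlmi
Title: Structural Perturbation Link Prediction for lncRNA-miRNA Bilayer Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts lncRNA-miRNA interactions by applying the structural
    perturbation method (first-order eigenvalue perturbation of a reduced
    adjacency matrix with fixed eigenvectors) to a bilayer network that
    integrates an lncRNA expression-similarity layer, an miRNA
    expression-similarity layer and the known bipartite interaction layer.
    Provides the structural-consistency index to quantify intrinsic link
    predictability of a network, k-fold cross-validated ROC/AUC evaluation
    of the prediction pipeline, and a group-structured synthetic data
    generator for end-to-end testing without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
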