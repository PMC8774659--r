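Package: ergcn
Title: Cancer Subtype Classification with Residual Graph Convolutional
    Networks on Patient Similarity Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies cancer patients into molecular subtypes from bulk
    gene-expression profiles. A patient similarity network is built by
    thresholding absolute pairwise Pearson correlations between expression
    profiles, and a two-layer graph convolutional network with a residual
    (linear skip) connection from the raw features — ERGCN — is trained
    transductively on that network. Includes the external classification
    metrics (accuracy, macro precision/recall/F1, multiclass Matthews
    correlation, pair-counting adjusted Rand index), internal clustering
    validity metrics (silhouette width, Davies-Bouldin index), repeated
    stratified 5-fold transductive cross-validation, a correlation-threshold
    sweep, leave-one-out evaluation of new samples via network augmentation,
    MLP/plain-GCN ablation variants, Gini-importance key-gene ranking via
    random forests, and a synthetic expression-data generator with known
    subtype structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    randomForest,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster
Config/testthat/edition: 3
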