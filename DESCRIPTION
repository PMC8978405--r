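Package: dtilink
Title: Drug-Target Interaction Link Prediction from Similarity-Network
    Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts drug-target interactions (DTIs) by embedding
    drug-drug and protein-protein similarity networks with biased
    second-order random walks and skip-gram negative sampling (node2vec),
    representing each drug-target pair as the concatenation of its two
    node embeddings, and classifying pairs with a gradient-boosted tree
    ensemble under a repeated, stratified cross-validation protocol.
    Includes MACCS/Tanimoto drug similarity, alignment-based protein
    similarity, activity-threshold labelling of bioactivity records,
    negative sampling from unknown pairs, ranked extraction of
    repurposing candidates, and a synthetic-data generator with planted
    cluster/family structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    methods,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
LinkingTo:
    Rcpp
Suggests:
    ChemmineOB,
    ChemmineR,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
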