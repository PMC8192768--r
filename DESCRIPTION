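Package: ALtox
Title: Somatic-Mutation-Based Prediction of Light-Chain Toxicity in AL Amyloidosis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes immunoglobulin lambda light chains as their somatic-mutation
    difference from the germline precursor under a progressive Kabat-Chothia
    numbering, derives sequence (AMP) and structure-contact (MAP, DAP) categorical
    features from a homodimeric light-chain structure, computes per-position
    Fisher-exact mutation-enrichment statistics, trains and cross-validates
    classifiers over a defined experiment grid with optional nominal SMOTE
    balancing, ranks features by information gain, and proposes minimal germline
    reversions that neutralize a predicted-toxic sequence. A repertoire simulator
    with planted discriminative mutations makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    bio3d,
    jsonlite,
    yaml,
    e1071,
    rpart,
    glmnet,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Classification, Proteomics, StructuralPrediction, FeatureExtraction
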