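Package: TextGraphNet
Title: Attention-Derived Graph Construction and Graph Neural Network
    Classification for Clinical Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Turns free-text histopathology reports into a homogeneous
    patient graph and classifies each patient node as metastatic or
    non-metastatic. Reports are tokenised and passed through a transformer
    encoder (a pretrained model or a deterministic stub); mean-pooled
    last-hidden-state embeddings become node features and layer/head-averaged
    attention statistics become scalar node scores. Features are reduced by
    consensus of three selectors (ANOVA F, extra-trees importance, TreeSHAP),
    nodes are grouped into same-class clusters by attention-score similarity
    to form edges, and a graph convolutional network with feedforward pre-
    and post-processing blocks performs two-class node classification.
    Includes a skip-connected feedforward baseline, a learning-rate finder,
    stratified splitting and cross-validation, ROC/AUC and calibration
    assessment, and a synthetic report corpus generator so the whole
    pipeline runs without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    ranger,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
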