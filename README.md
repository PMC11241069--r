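# TextGraphNet

Graph neural network classification of patients from free-text
histopathology reports.

Metastatic breast cancer is usually documented first in the pathologist's
narrative, not in structured fields. TextGraphNet turns a two-column table
of patient records — an identifier (`MR No`) and a free-text report
(`Hist_report`) — into a homogeneous patient graph and classifies every
node as metastatic (1) or non-metastatic (0). It is aimed at clinical
text-mining researchers who want the whole pipeline — transformer encoding,
feature selection, attention-based graph construction, graph-convolutional
classification, calibration assessment — as tested, configurable R
functions that run offline on synthetic data.

## The method

**Per-report features.** Each report is tokenised (WordPiece-style,
padded/truncated to `max_len`) and passed through a transformer encoder.
The document embedding is the mean-pooled last hidden state over the N real
tokens,

    MeanEmbedding = (1/N) * sum_i E_i ,

of which the first 767 of 768 components are retained as node features
(configurable `feature_width`).

**Per-report attention score.** The attention stack (layers × heads ×
tokens × tokens) is averaged over heads,

    A_ij = (1/H) * sum_h A_ij^(h) ,

then over layers; pad rows/columns are masked and the remaining entries are
summed into one scalar per report. Because every softmax row sums to 1 the
score sits on the token-count scale, which is what makes the graph
builder's integer threshold meaningful.

**Graph construction.** Within each (provisional) class, nodes are inserted
in ascending score order into running-mean groups: a node joins the first
group whose running mean lies within `node_threshold = 200` of its score,
linking to the group's current members; one parameter
`node_connections = 5` caps both the links a node may create and the group
size; a node no group admits seeds a new group. Edges never cross classes,
giving the homogeneous graph G = (V, E).

**Feature selection.** Embedding columns are scored by three selectors —
per-column ANOVA F, extra-trees impurity importance, and mean |TreeSHAP|
on the same extra-trees model — and the top 30 columns by mean rank are
kept.

**Classifier.** A feedforward pre-processing block (batch normalisation,
dropout, dense + GELU per stacked layer), two graph convolution layers
(hidden units [34, 34]; sum/mean/max neighbour aggregation with additive
skip connections), a feedforward post-processing block, and a two-class
softmax head; trained full-graph with Adam (learning rate 0.01, dropout
0.2, up to 300 epochs, early stopping on a validation split). A
skip-connected feedforward baseline (two blocks iterated four times) is
included, along with a learning-rate range finder, stratified 80/20
splitting, 3-fold cross-validation, ROC/AUC and calibration curves.

No public dataset exists for this task, so the package ships a synthetic
generator: class-conditional report vocabulary and lengths (or a direct
encoded dataset with class-shifted Gaussian features), plus a deterministic
stub encoder with the same output contract as a pretrained transformer —
nothing is downloaded.

## Worked example

```r
library(TextGraphNet)

# one report through the stub encoder at BERT-base geometry
enc <- stubEncoder(hidden_size = 768, n_layers = 12, n_heads = 12,
                   max_len = 64, seed = 7)
rec <- list(record_id = "MR00001",
            text = "invasive ductal carcinoma with metastatic deposit in
                    two axillary lymph nodes")
f <- extractReportFeatures(rec, enc, feature_width = 767)
length(f$values)   # 767   -- the retained embedding width
f$score            # 13    -- attention score = real token count

# full pipeline on the default synthetic study (1000 records, 767 columns)
cfg <- pipelineConfig()
cfg$seed <- 1L
res <- runPipeline(cfg)
res$report
#> EvalReport (n=200): accuracy 0.960, balanced accuracy 0.960, F1 0.960, AUC 0.987
res$graph
#> ReportGraph: 1000 nodes, 1994 edges, 30 features/node
#>   node_threshold=200, node_connections=5, 201 groups
head(res$selection$selected)
#> "f14" "f164" "f313" "f613" "f463" "f209"
```

The report means: on the held-out 20% (200 patients), 96% of nodes are
classified correctly, per-class recalls average 0.96, and the class
ranking is nearly perfect (AUC 0.987). The selected column ids recover the
five class-informative embedding dimensions planted by the generator
(f14, f164, f313, f463, f613). All artefacts (feature table, attention
scores, selection report, edge list, model archive, evaluation JSON,
ROC/calibration tables, run manifest with content hashes) are written to
`cfg$out_dir`.

A command-line front end with `simulate`, `encode`, `select`, `graph`,
`train`, `evaluate` and `run-all` subcommands is in
`inst/cli/textgraphnet.R`:

```sh
Rscript inst/cli/textgraphnet.R run-all --seed 1 --out out/
```

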