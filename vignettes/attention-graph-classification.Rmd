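---
title: "Attention-derived patient graphs for report classification: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-derived patient graphs for report classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(TextGraphNet)
```

TextGraphNet classifies patients as metastatic or non-metastatic from the
free text of their histopathology reports. This vignette is the package's
account of the science: the model and its assumptions, the parameters that
matter, what the synthetic data does and does not emulate, the numerical
choices, and the places where the design was genuinely open and a decision
had to be made.

## The model

The pipeline has four stages.

**1. Encoding.** Each report is tokenised (lowercased, split on
non-alphanumeric characters, long words broken into 8-character pieces,
hashed into a fixed vocabulary, wrapped in start/separator specials, padded
or truncated to `max_len`) and passed through a transformer encoder. Two
outputs are reduced per report: the *document embedding* — the mean of the
last hidden state over the N real (non-pad) tokens — and the *attention
score* — the attention stack averaged over heads, then layers, masked to
real rows and columns, then summed to a scalar. Padding is treated as
purely structural: pad rows and columns never contribute to any statistic,
and the suite checks that scrambling pad-position token ids changes no
output.

The underlying assumption is that reports of the two classes differ both in
content (which moves the mean embedding) and in how much attended material
they contain (which moves the score). Because every softmax-normalised
query row sums to one, the masked sum equals the real-token count, so the
score is, by construction, a length-flavoured statistic on the scale of
tokens.

**2. Feature selection.** The embedding columns (767 retained of a 768-wide
hidden state) are standardised to zero mean and unit variance, then scored
by three selectors: a per-column two-group ANOVA F statistic; impurity
importances of an extremely randomised trees ensemble
(`ranger`, `splitrule = "extratrees"`, whole sample, no bootstrap,
probability forest); and the per-column mean absolute TreeSHAP value of the
same ensemble. Rankings are combined by mean rank (ties to the lower column
index) and the top `k = 30` columns are kept. The F statistic was chosen
over a chi-squared score because embedding values are signed reals;
chi-squared would require non-negative features.

**3. Graph construction.** Nodes carry the selected features, a class, and
the attention score. Per class, nodes are inserted in ascending score order
(ties broken by record id) into groups that keep a running mean score. The
incoming node scans same-class groups in ascending running-mean order
(stable ties by creation order), skips full groups, and links to every
member of each group whose running mean lies within `node_threshold` of the
node's score, until its link budget is spent; it joins the first admitting
group (updating that group's running mean), and seeds a new singleton group
if none admits it. A single parameter `node_connections` caps both the
links a node may create and the group size. Edges never cross classes.

Insertion edges are stored directed (new node to existing member) with the
score gap at link time; for message passing they are symmetrised by
default (`graph.symmetrise`), since a "message from the node that arrived
later" is not physically meaningful here, and a directed variant is kept
for inspection.

**4. Classification.** The node classifier is: a feedforward
pre-processing block (per stacked layer: batch normalisation over the node
dimension, dropout, dense + GELU), two graph convolution layers, a
feedforward post-processing block, and a two-class softmax head. The graph
convolution is: message = linear transform of the neighbour state;
aggregation = sum (or mean/max) over incoming edges, a zero vector for
isolated nodes; update = GELU(dense([own state, aggregated message])) plus
an additive skip connection (identity, or a dense projection when widths
differ). Training is full-graph: integer-label cross-entropy on the
training nodes, Adam updates, early stopping on the accuracy of a
stratified 10% validation subset of the training split with best-weights
restore. A skip-connected feedforward baseline (two blocks joined by a
skip, the pair iterated four times with unshared weights) trains on
mini-batches.

All forward and backward passes are hand-written; the test suite verifies
every gradient against central finite differences (relative error below
1e-5) and the sum aggregation against the dense-adjacency matrix product.

## Parameters

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `encoder.max_len` | 512 | tokens | standard context length for the encoder family |
| `encoder.feature_width` | 767 | columns | retained prefix of the 768-wide hidden state (see below) |
| `selection.top_k` | 30 | columns | operating point of the published selection stage |
| `selection.n_trees` | 100 | trees | stable importances at desk scale |
| `selection.max_depth` | 10 | levels | keeps exact TreeSHAP on the same model fast; importances are insensitive to deeper trees on this data |
| `graph.node_threshold` | 200 | score units (≈ tokens) | maximum gap to a group's running mean |
| `graph.node_connections` | 5 | count | joint cap on per-node links and group size |
| `model.hidden_units` | [34, 34] | widths | graph-convolution layer sizes |
| `model.dropout` | 0.2 | rate | regularisation of the dense blocks |
| `train.learning_rate` | 0.01 | — | Adam step size |
| `train.epochs` | 300 | epochs | ceiling; early stopping normally ends sooner |
| `train.batch_size` | 128 | records | baseline and learning-rate finder only (see below) |
| `train.train_fraction` | 0.8 | — | stratified train share |
| `train.k_folds` | 3 | folds | cross-validation |
| `train.patience` | 50 | epochs | early-stopping patience on validation accuracy |

## Design decisions

These are the points where the printed protocol under-determines an
implementation; each decision is also exercised by tests.

* **767 versus 768.** The operative feature count is 767 although the
  encoder hidden state is 768-wide. We realise this as the first 767
  components of the mean embedding, fully configurable via
  `feature_width`; using the full 768 changes nothing structurally.
* **Node score: sum, not mean.** The score is described as an attention
  *average*, but a grouping threshold of 200 is incompatible with
  softmax-scale means (≤ 1). Only a statistic on the token-count scale
  makes that threshold meaningful, so the default is the masked **sum** of
  the layer/head-averaged matrix; `"mean"` and `"cls_row_sum"` are
  selectable via `encoder.score_method`.
* **Absolute gap.** Group admission uses |score − running mean| rather
  than the signed difference: the procedure is similarity grouping, and a
  signed rule would admit every node below a group's mean regardless of
  distance.
* **Dual cap.** One parameter caps both the inserted node's links and the
  group size, enforcing both readings of the connection limit.
* **Aggregation of the three selectors.** How the three selector rankings
  combine is unspecified; mean rank with ties to the lower column index is
  simple, scale-free, and treats the selectors symmetrically.
* **SHAP backend.** Exact path-dependent TreeSHAP on the extra-trees model
  itself, implemented as a small C++ kernel (the route the field's tree
  explanation packages take), cross-checked in the tests against exhaustive
  coalition enumeration and against local accuracy relative to ranger's
  own predictions. Sampling-based SHAP approximations were rejected as
  nondeterministic.
* **Full-batch graph training.** A batch size of 128 is incompatible with
  message passing over one graph, since a batch severs its out-of-batch
  edges; the graph model therefore trains full-graph, and the batch size
  applies to the baseline and the learning-rate finder.
* **Provisional classes without label leakage.** Graph construction is
  class-conditional, but using evaluation-node labels would leak them into
  the graph. By default held-out nodes receive the label of the nearer
  training-score centroid (ties to class 0); `graph.class_source =
  "true_labels"` reproduces the leaky variant deliberately.
* **Selection on training rows only.** The selectors consume labels, so the
  pipeline fits them on the training split and applies the chosen columns
  everywhere.
* **Baseline weights unshared.** Whether the baseline's four iterations
  share weights is unstated; unshared is the stronger model and the
  default.
* **Early stopping details.** Patience (50 epochs), validation share (10%
  of training, stratified) and the monitored metric (validation accuracy)
  are unstated in the protocol; the best parameters are always restored.
* **Split arithmetic.** The published node counts (813/187 of 1000) are not
  an 80/20 split; the package implements exact stratified 80/20
  (`round(0.8 * n_c)` per class), which yields 800/200.

## The synthetic data

No public corpus exists for this task (the original records are private),
so the generators define the study conditions:

* `generateReports()` emits 1000 records by default, balanced classes.
  Class-1 reports mix metastasis-flavoured marker phrases into a neutral
  histology vocabulary at an elevated rate (0.08 versus 0.005 per
  sentence-slot) and are longer — token counts are drawn from N(280, 60)
  versus N(120, 40), clipped to [10, 600] — so both the embedding channel
  and the attention-score (length) channel carry class signal, and lengths
  straddle typical `max_len` settings to exercise padding and truncation.
* `generateEncodedDataset()` bypasses text: 767 standard-normal columns of
  which five, spread evenly across the width, get a 3-sigma class mean
  shift; attention scores come from the same class-conditional normals.
  This is the default pipeline input and the fast path for tests.
* `stubEncoder()` is a deterministic transformer-shaped map (hash-derived
  token embeddings plus sinusoidal positions, low-rank per-head query/key
  projections, softmax attention over real tokens, residual
  attention-mixing between layers). It honours the full output contract of
  a pretrained encoder — shapes, row normalisation, bitwise determinism
  per seed — so every downstream stage is tested against it offline.

What passing tests on these data do show: the pipeline's mechanics are
correct (contracts, caps, gradients, metrics), and when class signal is
present in both channels the end-to-end system recovers it (held-out
accuracy and AUC ≥ 0.9 across seeds). What they do not show: performance
on real clinical language. Real reports have section structure, negation,
abbreviation noise and label noise that neither generator emulates, and a
pretrained encoder's attention statistics need not behave like the stub's
(in particular, the score's tight coupling to report length is a property
of softmax normalisation, which holds for real encoders too, but real
class-conditional length differences will be weaker).

## Numerical choices

* GELU is exact (`x * pnorm(x)`), not the tanh approximation; its
  derivative likewise.
* Batch normalisation uses population batch variance with eps = 1e-5 and
  running-statistic momentum 0.9; inference uses running statistics.
* Softmax rows are shifted by their maximum before exponentiation;
  cross-entropy clamps probabilities at 1e-12.
* Attention row softmax is computed over real tokens only.
* ANOVA F resolves 0/0 (constant column) to 0 and x/0 (perfect separation)
  to Inf, which ranks first.
* ROC thresholds are the unique scores plus sentinels; tied scores collapse
  to one point so the trapezoidal AUC counts ties as half-concordant, and
  it equals exhaustive pair counting (tested to 1e-10). Constant scores
  give AUC 0.5; single-class truth gives NA.
* Calibration uses 10 equal-width bins on [0, 1]; empty bins are omitted.
* The learning-rate finder suggests the steepest smoothed descent of loss
  against log learning rate, restricted to before the first divergence
  (loss above 4x the running minimum); a flat curve returns the first rate
  flagged weak.
* Degenerate inputs are first-class: empty reports error unless
  `keep_blank`; `node_connections = 0` yields an edgeless graph (and the
  classifier degrades to its feedforward path); an empty edge list writes a
  header-only file.
* Tie rules are explicit everywhere: selector ranks and selection order by
  lowest column index, provisional classes to class 0 at equidistance,
  insertion order by record id, threshold sweeps to the smallest candidate.

## Problem sizes

The test suite runs the full study size where the contract demands it
(selection cardinality at 1000 × 767; five end-to-end pipeline runs at the
default 1000 × 767; the graph builder at 500 nodes) and scales unit tests
down (corpora of 40–400 records, forests of 25–50 trees, oracle
equivalences at n ≤ 20 per instance, 100 instances per property). The
learning-rate finder and cross-validation are exercised at n = 40–90 with
shortened epoch budgets; their statistical behaviour at those sizes (tiny
validation subsets make the 0.5-threshold accuracy noisier than the
ranking) is why the k-fold test asserts primarily on AUC.

## Known limitations

* The encoder ships as a stub; plugging in a real pretrained transformer
  requires an offline weight source and is deliberately out of scope —
  `makeEncoder("<name>")` raises a configuration error naming the encoder.
* The attention score collapses a layers × heads × tokens × tokens object
  to one scalar per document; documents with similar lengths but different
  attention topology are indistinguishable to the graph builder.
* Graph construction is transductive: train and evaluation nodes share one
  graph (with provisional classes guarding labels). Inductive prediction
  on unseen nodes would need a fold-in step.
* The classifier head is strictly two-class.
* Batch normalisation statistics are computed over all nodes in the
  full-graph forward pass, a mild transductive coupling that is standard
  for this architecture family.
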