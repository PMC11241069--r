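#' @import methods
#' @importFrom stats rnorm runif rbinom sd var quantile setNames predict
#'   pnorm dnorm
#' @importFrom utils read.csv write.csv read.table write.table head tail
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame
#' @useDynLib TextGraphNet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Deterministic stub transformer encoder
#'
#' A transformer-shaped encoder whose parameters are a pure function of a
#' seed: hash-derived token embeddings plus sinusoidal positions, low-rank
#' per-head query/key projections, softmax attention over non-pad keys and
#' residual attention-mixing updates between layers. It implements the same
#' output contract as a pretrained encoder (per-token last-hidden-state
#' embeddings and a layers x heads x tokens x tokens attention stack with
#' softmax-normalised rows) so that every downstream stage can be exercised
#' deterministically and offline.
#'
#' @slot hiddenSize embedding width d (768 for BERT-base geometry)
#' @slot nLayers number of attention layers
#' @slot nHeads attention heads per layer
#' @slot maxLen padded sequence length
#' @slot headDim rank of the query/key projections
#' @slot seed integer seed all weights derive from
#' @slot vocabSize hashed vocabulary size of the tokeniser
#' @slot weights list of base projection matrices and per-(layer, head) scales
#' @exportClass StubEncoder
setClass("StubEncoder",
  representation(
    hiddenSize = "integer",
    nLayers    = "integer",
    nHeads     = "integer",
    maxLen     = "integer",
    headDim    = "integer",
    seed       = "integer",
    vocabSize  = "integer",
    weights    = "list"
  )
)

setValidity("StubEncoder", function(object) {
  msg <- character()
  if (object@hiddenSize < 1L) msg <- c(msg, "hiddenSize must be >= 1")
  if (object@nLayers < 1L) msg <- c(msg, "nLayers must be >= 1")
  if (object@nHeads < 1L) msg <- c(msg, "nHeads must be >= 1")
  if (object@maxLen < 2L) msg <- c(msg, "maxLen must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Container for encoded reports
#'
#' Extends \linkS4class{SummarizedExperiment}: the \code{"features"} assay
#' holds one mean-pooled embedding column per report (feature_width x n),
#' and \code{colData} carries the record identifier, the scalar node
#' attention score, and (when known) the class label.
#'
#' @exportClass EncodedReports
setClass("EncodedReports", contains = "SummarizedExperiment")

setValidity("EncodedReports", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  if (!"attention_score" %in% colnames(cd))
    msg <- c(msg, "colData must contain 'attention_score'")
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "an assay named 'features' is required")
  if ("attention_score" %in% colnames(cd) &&
      any(!is.finite(cd$attention_score)))
    msg <- c(msg, "attention scores must be finite")
  if (length(msg)) msg else TRUE
})

#' Homogeneous patient graph
#'
#' Nodes are patient records (feature vector + class label + attention
#' score); edges connect same-class nodes whose attention scores were within
#' the node threshold of a group's running mean at insertion time.
#'
#' @slot features numeric matrix, n nodes x k selected features
#' @slot labels integer vector in {0, 1}, one per node
#' @slot scores numeric attention score per node
#' @slot recordIds character node identifiers
#' @slot edges integer matrix with columns \code{from}, \code{to} (1-based
#'   node indices); directed insertion edges, new node -> existing member
#' @slot edgeGap numeric score gap |node score - group running mean| recorded
#'   when each edge was created
#' @slot groups list describing the final class-conditional groups
#' @slot params list: node_threshold, node_connections, symmetrise flag
#' @exportClass ReportGraph
setClass("ReportGraph",
  representation(
    features  = "matrix",
    labels    = "integer",
    scores    = "numeric",
    recordIds = "character",
    edges     = "matrix",
    edgeGap   = "numeric",
    groups    = "list",
    params    = "list"
  )
)

setValidity("ReportGraph", function(object) {
  msg <- character()
  n <- nrow(object@features)
  if (length(object@labels) != n) msg <- c(msg, "one label per node required")
  if (length(object@scores) != n) msg <- c(msg, "one score per node required")
  if (!all(object@labels %in% c(0L, 1L)))
    msg <- c(msg, "labels must be 0 or 1")
  if (nrow(object@edges) > 0L) {
    if (any(object@edges < 1L) || any(object@edges > n))
      msg <- c(msg, "edge endpoints must be valid node indices")
    if (any(object@edges[, 1L] == object@edges[, 2L]))
      msg <- c(msg, "self-loops are not allowed")
    key <- paste(object@edges[, 1L], object@edges[, 2L])
    if (anyDuplicated(key)) msg <- c(msg, "duplicate edges are not allowed")
    if (any(object@labels[object@edges[, 1L]] !=
            object@labels[object@edges[, 2L]]))
      msg <- c(msg, "edges must not cross classes")
  }
  if (nrow(object@edges) != length(object@edgeGap))
    msg <- c(msg, "one gap per edge required")
  if (length(msg)) msg else TRUE
})

#' Graph convolutional node classifier
#'
#' Holds the parameters of the two-class node classifier: a feedforward
#' pre-processing block (batch normalisation, dropout, dense + GELU per
#' stacked layer), two graph convolution layers with configurable
#' sum/mean/max neighbour aggregation and additive skip connections, a
#' feedforward post-processing block, and a softmax head. The same class
#' stores the skip-connected feedforward baseline (no graph input).
#'
#' @slot params nested list of weight matrices/vectors
#' @slot hyper list of hyperparameters (widths, aggregation, dropout, ...)
#' @slot kind "graph" or "baseline"
#' @slot trained logical
#' @slot history per-epoch training history (data.frame)
#' @exportClass GraphClassifier
setClass("GraphClassifier",
  representation(
    params  = "list",
    hyper   = "list",
    kind    = "character",
    trained = "logical",
    history = "data.frame"
  ),
  prototype(trained = FALSE, history = data.frame())
)

setValidity("GraphClassifier", function(object) {
  if (!object@kind %in% c("graph", "baseline"))
    return("kind must be 'graph' or 'baseline'")
  if (!object@hyper$aggregation %in% c("sum", "mean", "max"))
    return("aggregation must be sum, mean or max")
  TRUE
})

setMethod("show", "StubEncoder", function(object) {
  cat(sprintf(
    "StubEncoder: hidden=%d, layers=%d, heads=%d, max_len=%d, seed=%d\n",
    object@hiddenSize, object@nLayers, object@nHeads, object@maxLen,
    object@seed))
})

setMethod("show", "EncodedReports", function(object) {
  cat(sprintf("EncodedReports: %d reports x %d features\n",
              ncol(object), nrow(object)))
  sc <- SummarizedExperiment::colData(object)$attention_score
  cat(sprintf("  attention scores: [%.1f, %.1f]\n", min(sc), max(sc)))
  if ("label" %in% colnames(SummarizedExperiment::colData(object))) {
    tab <- table(SummarizedExperiment::colData(object)$label)
    cat("  labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
})

setMethod("show", "ReportGraph", function(object) {
  cat(sprintf(
    "ReportGraph: %d nodes, %d edges, %d features/node\n",
    nrow(object@features), nrow(object@edges), ncol(object@features)))
  cat(sprintf("  node_threshold=%g, node_connections=%d, %d groups\n",
              object@params$node_threshold, object@params$node_connections,
              length(object@groups)))
})

setMethod("show", "GraphClassifier", function(object) {
  cat(sprintf("GraphClassifier (%s): widths %s, aggregation '%s'%s\n",
              object@kind,
              paste(object@hyper$hidden_units, collapse = "/"),
              object@hyper$aggregation,
              if (object@trained) ", trained" else ""))
})
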