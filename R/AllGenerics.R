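#' @rdname encodeReport
#' @export
setGeneric("encodeReport", function(encoder, tok, ...)
  standardGeneric("encodeReport"))

#' Attention scores stored in an EncodedReports object
#' @param x an \linkS4class{EncodedReports}
#' @return numeric vector, one non-negative score per report
#' @export
setGeneric("attentionScores", function(x) standardGeneric("attentionScores"))

#' @rdname attentionScores
setMethod("attentionScores", "EncodedReports", function(x)
  setNames(SummarizedExperiment::colData(x)$attention_score, colnames(x)))

#' Class labels of an object holding labelled nodes
#' @param x an \linkS4class{EncodedReports} or \linkS4class{ReportGraph}
#' @return integer vector in {0, 1} (or NULL when unknown)
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))

setMethod("nodeLabels", "EncodedReports", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("label" %in% colnames(cd)) setNames(cd$label, colnames(x)) else NULL
})

setMethod("nodeLabels", "ReportGraph", function(x)
  setNames(x@labels, x@recordIds))

#' Node feature matrix of a graph (n nodes x k features)
#' @param x a \linkS4class{ReportGraph}
#' @export
setGeneric("nodeFeatures", function(x) standardGeneric("nodeFeatures"))

setMethod("nodeFeatures", "ReportGraph", function(x) {
  m <- x@features
  rownames(m) <- x@recordIds
  m
})

#' Edge list of a graph
#' @param x a \linkS4class{ReportGraph}
#' @param symmetrise add the reversed copy of every directed insertion edge
#'   (deduplicated); defaults to the flag the graph was built with
#' @return integer matrix with columns \code{from}, \code{to}
#' @export
setGeneric("edgeList", function(x, symmetrise = NULL)
  standardGeneric("edgeList"))

setMethod("edgeList", "ReportGraph", function(x, symmetrise = NULL) {
  if (is.null(symmetrise)) symmetrise <- isTRUE(x@params$symmetrise)
  e <- x@edges
  if (symmetrise && nrow(e) > 0L) {
    e <- rbind(e, e[, c(2L, 1L), drop = FALSE])
    e <- e[!duplicated(paste(e[, 1L], e[, 2L])), , drop = FALSE]
  }
  colnames(e) <- c("from", "to")
  e
})
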