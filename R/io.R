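# Readers and writers for the pipeline's table formats. All outputs are
# plain character-separated text and bit-stable given identical inputs.

tgn_log <- function(verbosity, level, fmt, ...) {
  ranks <- c(quiet = 0L, info = 1L, debug = 2L)
  if (ranks[[verbosity]] >= ranks[[level]]) message(sprintf(fmt, ...))
  invisible(NULL)
}

#' Read a reports table
#'
#' Expects a header with the identifier and report-text columns (defaults
#' "MR No" and "Hist_report"). Rows with a missing identifier or (by
#' default) blank text are dropped and each drop is logged; duplicate
#' identifiers are an error.
#'
#' @param path file path
#' @param id_col,text_col header names
#' @param sep field separator (default ",")
#' @param keep_blank keep rows with blank report text
#' @param verbosity "quiet", "info" or "debug"
#' @return list of records, each a list with \code{record_id} and
#'   \code{text}
#' @export
readReportsTable <- function(path, id_col = "MR No", text_col = "Hist_report",
                             sep = ",", keep_blank = FALSE,
                             verbosity = "info") {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 colClasses = "character")
  missing_cols <- setdiff(c(id_col, text_col), colnames(df))
  if (length(missing_cols))
    stop(sprintf("schema error: missing column(s) %s in %s",
                 paste(sprintf("'%s'", missing_cols), collapse = ", "), path))
  ids <- trimws(df[[id_col]])
  texts <- df[[text_col]]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (is.na(ids[i]) || !nzchar(ids[i])) {
      keep[i] <- FALSE
      tgn_log(verbosity, "info", "dropped row %d: missing record id", i)
    } else if (!keep_blank && (is.na(texts[i]) || !nzchar(trimws(texts[i])))) {
      keep[i] <- FALSE
      tgn_log(verbosity, "info", "dropped row %d (%s): blank report text",
              i, ids[i])
    }
  }
  ids <- ids[keep]; texts <- texts[keep]
  if (anyDuplicated(ids))
    stop(sprintf("duplicate record ids: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  mapply(function(id, tx) list(record_id = id, text = tx),
         ids, texts, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write a reports table (and optional labels file)
#' @param records list of records (record_id, text)
#' @param path output csv path
#' @param labels optional labels written to \code{labels_path}
#' @param labels_path defaults to \code{<path>.labels.csv}
#' @param id_col,text_col header names
#' @export
writeReportsTable <- function(records, path, labels = NULL,
                              labels_path = paste0(path, ".labels.csv"),
                              id_col = "MR No", text_col = "Hist_report") {
  df <- data.frame(
    id = vapply(records, `[[`, character(1L), "record_id"),
    text = vapply(records, `[[`, character(1L), "text"),
    check.names = FALSE)
  colnames(df) <- c(id_col, text_col)
  write.csv(df, path, row.names = FALSE)
  if (!is.null(labels)) {
    write.csv(data.frame(`MR No` = df[[id_col]], label = labels,
                         check.names = FALSE),
              labels_path, row.names = FALSE)
  }
  invisible(path)
}

#' Write the per-report feature table (one row per record, columns f0..)
#' @param x an \linkS4class{EncodedReports}
#' @param path output csv path
#' @export
writeFeatureTable <- function(x, path) {
  m <- featureMatrix(x)
  df <- data.frame(record_id = rownames(m), m, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write attention scores as a two-column table
#' @param x an \linkS4class{EncodedReports}
#' @param path output csv path
#' @export
writeAttentionScores <- function(x, path) {
  sc <- attentionScores(x)
  write.csv(data.frame(record_id = names(sc), score = unname(sc)),
            path, row.names = FALSE)
  invisible(path)
}

#' Write/read the edge list (tab-separated record ids, one edge per line)
#' @param graph a \linkS4class{ReportGraph}
#' @param path output path
#' @param symmetrise passed to \code{\link{edgeList}}
#' @export
writeEdgeList <- function(graph, path, symmetrise = NULL) {
  e <- edgeList(graph, symmetrise = symmetrise)
  df <- data.frame(source = graph@recordIds[e[, 1L]],
                   target = graph@recordIds[e[, 2L]])
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeEdgeList
#' @return \code{readEdgeList}: data.frame with source and target ids
#' @export
readEdgeList <- function(path) {
  read.table(path, sep = "\t", header = TRUE, colClasses = "character")
}

#' Export the adjacency matrix in coordinate (MatrixMarket) format
#' @param graph a \linkS4class{ReportGraph}
#' @param path output path
#' @param symmetrise passed to \code{\link{edgeList}}
#' @export
writeAdjacencyCOO <- function(graph, path, symmetrise = NULL) {
  e <- edgeList(graph, symmetrise = symmetrise)
  n <- length(graph@recordIds)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("%%MatrixMarket matrix coordinate integer general", con)
  writeLines(sprintf("%d %d %d", n, n, nrow(e)), con)
  if (nrow(e))
    writeLines(sprintf("%d %d 1", e[, 1L], e[, 2L]), con)
  invisible(path)
}

#' Write the feature-selection report
#' @param selection result of \code{\link{selectFeatures}} /
#'   \code{\link{aggregateAndSelect}}
#' @param path output csv path
#' @export
writeSelectionReport <- function(selection, path) {
  write.csv(selection$table, path, row.names = FALSE)
  invisible(path)
}

#' Write an EvalReport as JSON (ROC and calibration as csv side tables)
#' @param report an \code{EvalReport}
#' @param path output json path
#' @export
writeEvalReport <- function(report, path) {
  scalar <- report[c("accuracy", "balanced_accuracy", "f1", "auc", "n")]
  jsonlite::write_json(scalar, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (!is.null(report$roc))
    write.csv(report$roc, sub("\\.json$", ".roc.csv", path),
              row.names = FALSE)
  write.csv(report$calibration, sub("\\.json$", ".calibration.csv", path),
            row.names = FALSE)
  invisible(path)
}

#' Save / load a fitted classifier
#'
#' The parameters go to an RDS archive; a JSON manifest of the
#' hyperparameters is written alongside.
#'
#' @param model a \linkS4class{GraphClassifier}
#' @param path archive path (".rds" appended if absent)
#' @export
saveModel <- function(model, path) {
  if (!grepl("\\.rds$", path)) path <- paste0(path, ".rds")
  saveRDS(list(params = model@params, hyper = model@hyper,
               kind = model@kind, trained = model@trained), path)
  jsonlite::write_json(
    c(model@hyper, list(kind = model@kind, trained = model@trained)),
    sub("\\.rds$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  x <- readRDS(path)
  new("GraphClassifier", params = x$params, hyper = x$hyper, kind = x$kind,
      trained = x$trained)
}
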