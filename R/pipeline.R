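# Configuration handling and the end-to-end pipeline:
# encode -> select -> build graph -> train -> evaluate.

#' Default pipeline configuration
#'
#' Nested configuration covering every stage. Defaults reproduce the
#' published settings: 767-wide embeddings, top-30 feature selection,
#' node threshold 200 and node connections 5, hidden units [34, 34],
#' learning rate 0.01, dropout 0.2, 300 epochs, batch size 128, 3 folds,
#' 80/20 split, 1000 synthetic records.
#'
#' @return nested list of configuration keys
#' @export
pipelineConfig <- function() {
  list(
    seed = 1L,
    out_dir = "tgn-output",
    verbosity = "info",
    input = list(path = NULL, id_col = "MR No", text_col = "Hist_report",
                 sep = ",", labels_path = NULL),
    synthetic = list(enabled = TRUE, mode = "encoded", n = 1000L,
                     class_balance = 0.5, p = 767L,
                     informative_dims = NULL, effect_size = 3,
                     noise_sd = 1),
    encoder = list(name = "stub", stub_seed = 7L, max_len = 512L,
                   feature_width = 767L, hidden_size = 768L,
                   n_layers = 12L, n_heads = 12L, score_method = "sum"),
    selection = list(top_k = 30L, n_trees = 100L, seed = 11L,
                     max_depth = 10L),
    graph = list(node_threshold = 200, node_connections = 5L,
                 symmetrise = TRUE, class_source = "centroid"),
    model = list(hidden_units = c(34L, 34L), aggregation = "sum",
                 dropout = 0.2, ffn_stack_depth = 3L),
    train = list(learning_rate = 0.01, epochs = 300L, batch_size = 128L,
                 k_folds = 3L, train_fraction = 0.8, patience = 50L,
                 val_fraction = 0.1, run_cv = FALSE)
  )
}

merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base))
      stop(sprintf("unknown configuration key: %s", full))
    if (is.list(base[[key]]) && !is.null(base[[key]])) {
      if (!is.list(override[[key]]))
        stop(sprintf("configuration key %s must be a mapping", full))
      base[[key]] <- merge_config(base[[key]], override[[key]], full)
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Read a pipeline configuration file
#'
#' A YAML file with the nested keys of \code{\link{pipelineConfig}}; unknown
#' keys are rejected, missing keys keep their defaults.
#'
#' @param path yaml file path (NULL for pure defaults)
#' @param overrides named list merged on top of the file values
#' @export
readPipelineConfig <- function(path = NULL, overrides = list()) {
  cfg <- pipelineConfig()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  if (length(overrides)) cfg <- merge_config(cfg, overrides)
  cfg
}

run_stage <- function(name, verbosity, expr) {
  tgn_log(verbosity, "info", "[%s] ...", name)
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full pipeline
#'
#' Executes encode, select, build-graph, train, evaluate, and writes every
#' artefact (feature table, attention scores, selection report, edge list,
#' model archive, evaluation report, ROC/calibration tables, training
#' history) plus a run manifest (configuration, seed, content hashes) to the
#' output directory.
#'
#' @param cfg configuration list (see \code{\link{pipelineConfig}})
#' @return invisibly, a list with the artefact paths, the evaluation report
#'   and the main objects
#' @export
runPipeline <- function(cfg = pipelineConfig()) {
  v <- cfg$verbosity
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)

  enc <- run_stage("encode", v, {
    if (!is.null(cfg$input$path)) {
      records <- readReportsTable(cfg$input$path, cfg$input$id_col,
                                  cfg$input$text_col, cfg$input$sep,
                                  verbosity = v)
      labels <- NULL
      if (!is.null(cfg$input$labels_path)) {
        lab <- read.csv(cfg$input$labels_path, check.names = FALSE)
        labels <- as.integer(lab$label[match(
          vapply(records, `[[`, character(1L), "record_id"),
          trimws(as.character(lab[[1L]])))])
      }
      encoder <- makeEncoder(cfg$encoder$name,
                             hidden_size = cfg$encoder$hidden_size,
                             n_layers = cfg$encoder$n_layers,
                             n_heads = cfg$encoder$n_heads,
                             max_len = cfg$encoder$max_len,
                             seed = cfg$encoder$stub_seed)
      encodeReports(records, encoder,
                    feature_width = cfg$encoder$feature_width,
                    labels = labels,
                    score_method = cfg$encoder$score_method)
    } else if (isTRUE(cfg$synthetic$enabled) &&
               identical(cfg$synthetic$mode, "encoded")) {
      generateEncodedDataset(syntheticConfig(
        n = cfg$synthetic$n, class_balance = cfg$synthetic$class_balance,
        p = cfg$synthetic$p,
        informative_dims = cfg$synthetic$informative_dims,
        effect_size = cfg$synthetic$effect_size,
        noise_sd = cfg$synthetic$noise_sd, seed = seed))
    } else if (isTRUE(cfg$synthetic$enabled)) {
      sim <- generateReports(syntheticConfig(
        n = cfg$synthetic$n, class_balance = cfg$synthetic$class_balance,
        seed = seed))
      encoder <- makeEncoder(cfg$encoder$name,
                             hidden_size = cfg$encoder$hidden_size,
                             n_layers = cfg$encoder$n_layers,
                             n_heads = cfg$encoder$n_heads,
                             max_len = cfg$encoder$max_len,
                             seed = cfg$encoder$stub_seed)
      encodeReports(sim$records, encoder,
                    feature_width = cfg$encoder$feature_width,
                    labels = sim$labels,
                    score_method = cfg$encoder$score_method)
    } else {
      stop("no input: set input.path or synthetic.enabled")
    }
  })
  y <- nodeLabels(enc)
  if (is.null(y)) stop("labels are required to train and evaluate")
  X <- featureMatrix(enc)
  scores <- attentionScores(enc)

  split <- run_stage("split", v,
    splitDataset(y, cfg$train$train_fraction, seed = seed))

  sel <- run_stage("select", v, {
    # selectors see training rows only; the chosen columns apply everywhere
    s <- selectFeatures(X[split$train, , drop = FALSE], y[split$train],
                        k = cfg$selection$top_k,
                        n_trees = cfg$selection$n_trees,
                        seed = cfg$selection$seed,
                        max_depth = cfg$selection$max_depth)
    s
  })
  Xn <- normaliseFeatures(X)[, sel$selected, drop = FALSE]

  graph <- run_stage("graph", v, {
    cls <- if (identical(cfg$graph$class_source, "true_labels"))
      assignProvisionalClass(scores, split$train, y[split$train],
                             method = "true_labels", all_labels = y)
    else
      assignProvisionalClass(scores, split$train, y[split$train])
    buildGraph(Xn, cls, scores, record_ids = colnames(enc),
               node_threshold = cfg$graph$node_threshold,
               node_connections = cfg$graph$node_connections,
               symmetrise = cfg$graph$symmetrise)
  })

  tcfg <- trainConfig(learning_rate = cfg$train$learning_rate,
                      dropout = cfg$model$dropout,
                      epochs = cfg$train$epochs,
                      batch_size = cfg$train$batch_size,
                      k_folds = cfg$train$k_folds,
                      train_fraction = cfg$train$train_fraction,
                      patience = cfg$train$patience,
                      val_fraction = cfg$train$val_fraction,
                      seed = seed)
  fit <- run_stage("train", v, {
    model <- initGraphClassifier(ncol(Xn),
                                 hidden_units = cfg$model$hidden_units,
                                 dropout = cfg$model$dropout,
                                 ffn_stack_depth = cfg$model$ffn_stack_depth,
                                 aggregation = cfg$model$aggregation,
                                 seed = seed)
    trainClassifier(model, Xn, y, split$train, tcfg,
                    edges = edgeList(graph))
  })

  report <- run_stage("evaluate", v, {
    probs <- modelForward(fit, Xn, edgeList(graph))
    computeMetrics(y[split$test], probs[split$test, , drop = FALSE])
  })

  cv <- NULL
  if (isTRUE(cfg$train$run_cv)) {
    cv <- run_stage("cross-validate", v,
      kfoldCV(Xn, y, scores, tcfg,
              node_threshold = cfg$graph$node_threshold,
              node_connections = cfg$graph$node_connections,
              hidden_units = cfg$model$hidden_units,
              aggregation = cfg$model$aggregation))
  }

  paths <- run_stage("write", v, {
    p <- list(
      features = writeFeatureTable(enc, file.path(out, "features.csv")),
      scores = writeAttentionScores(enc, file.path(out, "scores.csv")),
      selection = writeSelectionReport(sel, file.path(out, "selection.csv")),
      edges = writeEdgeList(graph, file.path(out, "edges.tsv")),
      adjacency = writeAdjacencyCOO(graph, file.path(out, "adjacency.mtx")),
      model = saveModel(fit, file.path(out, "model.rds")),
      history = {
        write.csv(fit@history, file.path(out, "history.csv"),
                  row.names = FALSE)
        file.path(out, "history.csv")
      },
      eval = writeEvalReport(report, file.path(out, "eval.json")))
    if (!is.null(cv)) {
      jsonlite::write_json(
        list(mean_accuracy = cv$mean_accuracy, mean_auc = cv$mean_auc),
        file.path(out, "cv.json"), auto_unbox = TRUE, digits = NA)
      p$cv <- file.path(out, "cv.json")
    }
    p
  })

  manifest <- list(config = cfg, seed = seed,
                   package_version = as.character(
                     utils::packageVersion("TextGraphNet")),
                   files = as.list(tools::md5sum(unlist(paths))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  tgn_log(v, "info", "done: %s", out)
  invisible(list(paths = paths, report = report, cv = cv, graph = graph,
                 model = fit, selection = sel, split = split,
                 encoded = enc))
}
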