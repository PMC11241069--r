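# Training protocol: stratified splitting, supervised training with Adam and
# early stopping, learning-rate range finding, stratified k-fold
# cross-validation.

#' Training configuration
#'
#' Defaults follow the published protocol: learning rate 0.01, dropout 0.2,
#' 300 epochs, batch size 128 (used by the baseline and the learning-rate
#' finder; the graph model trains full-batch since message passing needs the
#' whole graph), 3 folds, 80/20 train/test split.
#'
#' @param learning_rate Adam learning rate
#' @param dropout dropout rate
#' @param epochs maximum epochs
#' @param batch_size mini-batch size for non-graph training
#' @param k_folds folds for cross-validation
#' @param train_fraction training share of the data
#' @param patience early-stopping patience (epochs past the best validation
#'   metric); the best parameters are restored
#' @param val_fraction share of the training split held out for early
#'   stopping
#' @param seed RNG seed for splits, dropout and initialisation
#' @export
trainConfig <- function(learning_rate = 0.01, dropout = 0.2, epochs = 300L,
                        batch_size = 128L, k_folds = 3L,
                        train_fraction = 0.8, patience = 50L,
                        val_fraction = 0.1, seed = 1L) {
  stopifnot(learning_rate >= 0, epochs >= 1L, batch_size >= 1L,
            k_folds >= 2L, train_fraction > 0, train_fraction < 1,
            patience >= 0L, val_fraction > 0, val_fraction < 1)
  structure(list(learning_rate = learning_rate, dropout = dropout,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 k_folds = as.integer(k_folds),
                 train_fraction = train_fraction,
                 patience = as.integer(patience),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "TrainConfig")
}

#' Stratified train/test split
#'
#' \code{round(train_fraction * n_c)} training records per class (preserving
#' class proportions within one record), disjoint and covering.
#'
#' @param labels class labels (used for stratification)
#' @param train_fraction training share (default 0.8)
#' @param seed RNG seed
#' @param stratified preserve per-class proportions (default TRUE)
#' @return list with integer index vectors \code{train} and \code{test}
#' @export
splitDataset <- function(labels, train_fraction = 0.8, seed = 1L,
                         stratified = TRUE) {
  n <- length(labels)
  stopifnot(n >= 2L, train_fraction > 0, train_fraction < 1)
  with_local_seed(seed, {
    if (stratified) {
      classes <- unique(labels)
      if (length(classes) < 2L)
        stop("stratified split impossible: only one class present")
      train <- integer(0L)
      for (c in classes) {
        idx <- which(labels == c)
        n_tr <- round(train_fraction * length(idx))
        if (n_tr == 0L || n_tr == length(idx))
          stop("stratified split impossible: a class would be empty")
        train <- c(train, sample(idx, n_tr))
      }
    } else {
      train <- sample(n, round(train_fraction * n))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_len(n), train))
  })
}

#' Train a classifier
#'
#' Full-graph forward passes per step for the graph model (mini-batches of
#' \code{cfg$batch_size} for the baseline), integer-label cross-entropy,
#' Adam updates, early stopping on validation accuracy with best-weights
#' restore.
#'
#' @param model an untrained \linkS4class{GraphClassifier}
#' @param X n x k feature matrix
#' @param y labels in {0, 1} for all nodes (only \code{train_idx} rows are
#'   used for fitting)
#' @param train_idx indices of training nodes
#' @param cfg a \code{\link{trainConfig}}
#' @param edges edge matrix (from, to) for the graph model
#' @param quiet suppress progress messages
#' @return the fitted \linkS4class{GraphClassifier} (history in
#'   \code{@history})
#' @export
trainClassifier <- function(model, X, y, train_idx, cfg = trainConfig(),
                            edges = NULL, quiet = TRUE) {
  stopifnot(is(model, "GraphClassifier"), nrow(X) == length(y))
  y <- as.integer(y)
  if (is.null(edges)) edges <- matrix(integer(0L), 0L, 2L)
  hyper <- model@hyper
  hyper$dropout <- cfg$dropout
  kind <- model@kind
  params <- model@params

  # stratified validation subset of the training split for early stopping
  vsplit <- splitDataset(y[train_idx], train_fraction = 1 - cfg$val_fraction,
                         seed = cfg$seed + 1L)
  fit_idx <- train_idx[vsplit$train]
  val_idx <- train_idx[vsplit$test]

  state <- adam_init(params)
  best <- list(metric = -Inf, params = params, epoch = 0L)
  hist <- data.frame(epoch = integer(0L), loss = numeric(0L),
                     val_accuracy = numeric(0L))
  with_local_seed(cfg$seed + 2L, {
    for (epoch in seq_len(cfg$epochs)) {
      if (kind == "graph") {
        step <- model_grad(params, hyper, kind, X, edges, y, fit_idx,
                           training = TRUE)
        if (!is.finite(step$loss))
          stop(sprintf("NaN loss at epoch %d: try a smaller learning rate",
                       epoch))
        params <- step$params  # running statistics updated
        upd <- adam_step(params, step$grads, state, cfg$learning_rate)
        params <- upd$params; state <- upd$state
        epoch_loss <- step$loss
      } else {
        sh <- sample(fit_idx)
        batches <- split(sh, ceiling(seq_along(sh) / cfg$batch_size))
        losses <- numeric(0L)
        for (b in batches) {
          step <- model_grad(params, hyper, kind,
                             X[b, , drop = FALSE], edges,
                             y[b], seq_along(b), training = TRUE)
          if (!is.finite(step$loss))
            stop(sprintf("NaN loss at epoch %d: try a smaller learning rate",
                         epoch))
          params <- step$params
          upd <- adam_step(params, step$grads, state, cfg$learning_rate)
          params <- upd$params; state <- upd$state
          losses <- c(losses, step$loss)
        }
        epoch_loss <- mean(losses)
      }
      fw <- model_forward_full(params, hyper, kind, X, edges,
                               training = FALSE)
      val_acc <- mean((fw$probs[val_idx, 2L] >= 0.5) == (y[val_idx] == 1L))
      hist <- rbind(hist, data.frame(epoch = epoch, loss = epoch_loss,
                                     val_accuracy = val_acc))
      if (val_acc > best$metric) {
        best <- list(metric = val_acc, params = params, epoch = epoch)
      } else if (epoch - best$epoch > cfg$patience) {
        if (!quiet)
          message(sprintf("early stop at epoch %d (best epoch %d)",
                          epoch, best$epoch))
        break
      }
    }
  })
  model@params <- best$params
  model@trained <- TRUE
  model@history <- hist
  model
}

#' Learning-rate range finder
#'
#' Runs one optimisation step per point of a geometric learning-rate
#' schedule (one mini-batch each; the full graph for the graph model) and
#' records the loss. The suggested rate is the one where the smoothed loss
#' decreases fastest with respect to log learning rate, restricted to before
#' the first divergence (loss above 4x the running minimum). A flat curve
#' yields the first index, flagged weak.
#'
#' @param model_factory function() returning a fresh untrained
#'   \linkS4class{GraphClassifier}
#' @param X,y,edges the data
#' @param lr_min,lr_max schedule endpoints (lr_min < lr_max)
#' @param steps schedule length (>= 2)
#' @param batch_size rows per step for non-graph models
#' @param seed RNG seed
#' @return list with \code{table} (step, lr, loss), \code{suggested_lr},
#'   and \code{weak} flag
#' @export
lrFinder <- function(model_factory, X, y, edges = NULL, lr_min = 1e-4,
                     lr_max = 1, steps = 30L, batch_size = 128L, seed = 1L) {
  stopifnot(lr_min < lr_max, steps >= 2L)
  model <- model_factory()
  params <- model@params
  hyper <- model@hyper
  kind <- model@kind
  if (is.null(edges)) edges <- matrix(integer(0L), 0L, 2L)
  y <- as.integer(y)
  lrs <- lr_min * (lr_max / lr_min)^((seq_len(steps) - 1) / (steps - 1))
  state <- adam_init(params)
  losses <- numeric(steps)
  with_local_seed(seed, {
    for (t in seq_len(steps)) {
      idx <- if (kind == "graph") seq_len(nrow(X))
             else sample(nrow(X), min(batch_size, nrow(X)))
      step <- model_grad(params, hyper, kind, X[idx, , drop = FALSE], edges,
                         y[idx], seq_along(idx), training = TRUE)
      losses[t] <- step$loss
      if (!is.finite(step$loss)) break
      params <- step$params
      upd <- adam_step(params, step$grads, state, lrs[t])
      params <- upd$params; state <- upd$state
    }
  })
  tab <- data.frame(step = seq_len(steps), lr = lrs, loss = losses)
  sug <- suggest_lr(lrs, losses)
  list(table = tab, suggested_lr = sug$lr, weak = sug$weak)
}

# stratified fold assignment: per class, shuffled indices dealt round-robin;
# the dealing position carries over between classes so overall fold sizes
# also differ by at most one
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_local_seed(seed, {
    offset <- 0L
    for (c in unique(y)) {
      idx <- sample(which(y == c))
      fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- offset + length(idx)
    }
  })
  fold
}

# steepest smoothed descent of loss w.r.t. log-lr, before first divergence
# (loss > 4 x running minimum)
suggest_lr <- function(lrs, losses) {
  valid <- which(is.finite(losses) &
                 losses <= 4 * cummin(replace(losses, !is.finite(losses),
                                              Inf)))
  if (length(valid) < 2L) return(list(lr = NA_real_, weak = TRUE))
  last <- max(valid)
  sm <- stats::filter(losses[seq_len(last)], rep(1 / 3, 3L), sides = 2L)
  sm[is.na(sm)] <- losses[seq_len(last)][is.na(sm)]
  slope <- diff(as.numeric(sm)) / diff(log(lrs[seq_len(last)]))
  i <- which.min(slope)
  list(lr = lrs[i], weak = !is.finite(min(slope)) || min(slope) >= 0)
}

#' Stratified k-fold cross-validation
#'
#' Stratified folds (sizes differing by at most one); per fold the graph is
#' rebuilt using only the training fold's labels (held-out nodes get
#' provisional nearest-centroid classes), a fresh model is trained, and the
#' held-out fold is scored.
#'
#' @param features n x k matrix
#' @param y labels
#' @param scores node attention scores
#' @param cfg a \code{\link{trainConfig}}
#' @param k folds (default \code{cfg$k_folds})
#' @param node_threshold,node_connections graph parameters
#' @param hidden_units,aggregation model parameters
#' @return list with \code{folds} (EvalReports), \code{mean_accuracy},
#'   \code{mean_auc}, \code{fold_assignment}
#' @export
kfoldCV <- function(features, y, scores, cfg = trainConfig(),
                    k = cfg$k_folds, node_threshold = 200,
                    node_connections = 5L, hidden_units = c(34L, 34L),
                    aggregation = "sum") {
  n <- length(y)
  stopifnot(k >= 2L, n >= k)
  y <- as.integer(y)
  fold <- stratified_folds(y, k, cfg$seed + 3L)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(fold == f)
    train_idx <- which(fold != f)
    cls <- assignProvisionalClass(scores, train_idx, y[train_idx])
    graph <- buildGraph(features, cls, scores,
                        node_threshold = node_threshold,
                        node_connections = node_connections)
    model <- initGraphClassifier(ncol(features), hidden_units,
                                 dropout = cfg$dropout,
                                 aggregation = aggregation,
                                 seed = cfg$seed + f)
    fit <- trainClassifier(model, features, y, train_idx, cfg,
                           edges = edgeList(graph))
    probs <- modelForward(fit, features, edgeList(graph))
    reports[[f]] <- computeMetrics(y[test_idx],
                                   probs[test_idx, , drop = FALSE])
  }
  list(folds = reports,
       mean_accuracy = mean(vapply(reports, `[[`, numeric(1L), "accuracy")),
       mean_auc = mean(vapply(reports, `[[`, numeric(1L), "auc")),
       fold_assignment = fold)
}
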