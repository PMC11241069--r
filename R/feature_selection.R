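# Three-selector feature reduction: per-column ANOVA F, extra-trees impurity
# importance, and mean |TreeSHAP| on the same extra-trees model, combined by
# mean-rank consensus.

#' Standardise feature columns
#'
#' Shifts and scales every column to zero mean and unit variance (sample
#' variance, denominator n - 1); constant columns map to all-zero.
#'
#' @param X numeric matrix, records x features
#' @return scaled matrix with \code{"center"} and \code{"scale"} attributes
#' @export
normaliseFeatures <- function(X) {
  stopifnot(is.matrix(X), nrow(X) >= 2L)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  scl0 <- ifelse(scl < 1e-12, 1, scl)
  out <- sweep(sweep(X, 2L, ctr), 2L, scl0, `/`)
  out[, scl < 1e-12] <- 0
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl0
  out
}

new_selector_ranking <- function(selector, score, column_ids) {
  # ranks 1 = most relevant; ties broken by lowest column index
  rk <- rank(-score, ties.method = "first")
  structure(list(selector = selector,
                 score = setNames(score, column_ids),
                 rank = setNames(as.integer(rk), column_ids),
                 column_ids = column_ids),
            class = "SelectorRanking")
}

#' Univariate feature scores (one-way ANOVA F)
#'
#' For each column, the two-group ANOVA F statistic between class 0 and
#' class 1 values; larger = more class-separating. A constant column
#' (0/0) scores 0 by convention; zero within-class variance with non-zero
#' between-class variance scores Inf (perfect separation).
#'
#' @param X records x features matrix
#' @param y labels in {0, 1}
#' @return a \code{SelectorRanking}
#' @export
univariateScores <- function(X, y) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop("univariate scores need both classes present in y")
  n <- nrow(X)
  g0 <- y == 0L
  n0 <- sum(g0); n1 <- n - n0
  m0 <- colMeans(X[g0, , drop = FALSE])
  m1 <- colMeans(X[!g0, , drop = FALSE])
  m <- colMeans(X)
  ss_between <- n0 * (m0 - m)^2 + n1 * (m1 - m)^2
  ss_within <- colSums(sweep(X[g0, , drop = FALSE], 2L, m0)^2) +
    colSums(sweep(X[!g0, , drop = FALSE], 2L, m1)^2)
  f <- (ss_between / 1) / (ss_within / (n - 2L))
  tol <- 1e-24
  f[ss_within < tol & ss_between < tol] <- 0
  f[ss_within < tol & ss_between >= tol] <- Inf
  ids <- colnames(X)
  if (is.null(ids)) ids <- paste0("f", seq_len(ncol(X)) - 1L)
  new_selector_ranking("univariate_f", unname(f), ids)
}

#' Fit the extra-trees model and extract impurity importances
#'
#' Extremely randomised trees (ranger, \code{splitrule = "extratrees"},
#' whole-sample, no bootstrap) fit as a probability forest; mean
#' impurity-decrease importances are normalised to sum to 1.
#'
#' @param X records x features matrix
#' @param y labels in {0, 1}
#' @param n_trees ensemble size (default 100)
#' @param seed integer seed
#' @param max_depth tree depth cap (default 10; keeps the exact SHAP pass
#'   on the same model tractable)
#' @return a \code{SelectorRanking} whose \code{model} element carries the
#'   fitted forest for \code{\link{shapImportance}}
#' @export
extraTreesImportance <- function(X, y, n_trees = 100L, seed = 1L,
                                 max_depth = 10L) {
  stopifnot(is.matrix(X), n_trees >= 1L)
  ids <- colnames(X)
  if (is.null(ids)) ids <- paste0("f", seq_len(ncol(X)) - 1L)
  df <- as.data.frame(X)
  colnames(df) <- ids
  fit <- ranger::ranger(
    x = df, y = factor(y, levels = c(0L, 1L)),
    num.trees = n_trees, splitrule = "extratrees", num.random.splits = 1L,
    replace = FALSE, sample.fraction = 1, probability = TRUE,
    importance = "impurity", max.depth = max_depth, seed = seed,
    num.threads = 1L)
  imp <- fit$variable.importance[ids]
  imp <- pmax(imp, 0)
  tot <- sum(imp)
  if (tot > 0) imp <- imp / tot
  out <- new_selector_ranking("extra_trees", unname(imp), ids)
  out$model <- fit
  out
}

# Flatten a ranger forest into the arrays the C++ kernels consume.
# Leaf value = class-1 probability; covers are computed by routing X.
flatten_forest <- function(fit, X) {
  n_trees <- fit$num.trees
  lefts <- rights <- feats <- list()
  thrs <- vals <- list()
  offsets <- integer(n_trees + 1L)
  for (t in seq_len(n_trees)) {
    ti <- ranger::treeInfo(fit, t)
    leaf <- ti$terminal
    lefts[[t]] <- ifelse(leaf, -1L, ti$leftChild)
    rights[[t]] <- ifelse(leaf, -1L, ti$rightChild)
    feats[[t]] <- ifelse(leaf, 0L, ti$splitvarID)
    thrs[[t]] <- ifelse(leaf, 0, ti$splitval)
    v <- if ("pred.1" %in% names(ti)) ti$pred.1 else ti$prediction
    vals[[t]] <- ifelse(leaf, v, 0)
    offsets[t + 1L] <- offsets[t] + nrow(ti)
  }
  left <- as.integer(unlist(lefts)); right <- as.integer(unlist(rights))
  feature <- as.integer(unlist(feats))
  threshold <- as.numeric(unlist(thrs)); value <- as.numeric(unlist(vals))
  cover <- .tree_covers_cpp(X, left, right, feature, threshold, offsets)
  list(left = left, right = right, feature = feature, threshold = threshold,
       value = value, cover = cover, tree_start = offsets)
}

#' Mean absolute SHAP importance
#'
#' Exact path-dependent TreeSHAP attribution of the extra-trees model's
#' class-1 probability, averaged (absolute values) over records. Satisfies
#' local accuracy: per record, sum of SHAP values + base value equals the
#' forest output.
#'
#' @param model a fitted ranger forest (as returned inside
#'   \code{\link{extraTreesImportance}}) or a \code{SelectorRanking} carrying
#'   one
#' @param X the records x features matrix the model was fitted on
#' @param rows optional subset of record indices to attribute (default all)
#' @return a \code{SelectorRanking}; elements \code{phi} (attribution matrix
#'   for the attributed rows) and \code{base} are attached
#' @export
shapImportance <- function(model, X, rows = NULL) {
  if (inherits(model, "SelectorRanking")) model <- model$model
  stopifnot(inherits(model, "ranger"), is.matrix(X))
  ids <- colnames(X)
  if (is.null(ids)) ids <- paste0("f", seq_len(ncol(X)) - 1L)
  vars <- model$forest$independent.variable.names
  if (length(vars) != ncol(X) || !all(vars == ids))
    stop("model/feature mismatch: the model was not fitted on X's columns")
  fo <- flatten_forest(model, X)
  rows <- if (is.null(rows)) seq_len(nrow(X)) else rows
  res <- .treeshap_cpp(X[rows, , drop = FALSE], fo$left, fo$right,
                       fo$feature, fo$threshold, fo$value, fo$cover,
                       fo$tree_start)
  score <- colMeans(abs(res$phi))
  out <- new_selector_ranking("shap", score, ids)
  out$phi <- res$phi
  out$base <- res$base
  out
}

#' Aggregate selector rankings and keep the top-k columns
#'
#' Columns are ordered by their mean rank across the selectors (ties broken
#' by lowest column index) and the first \code{k} are retained.
#'
#' @param rankings list of \code{SelectorRanking} objects over the same
#'   columns
#' @param k number of columns to keep (default 30)
#' @return list with \code{selected} (column ids, in mean-rank order),
#'   \code{mean_rank}, and a per-column summary \code{table}
#' @export
aggregateAndSelect <- function(rankings, k = 30L) {
  stopifnot(length(rankings) >= 1L)
  ids <- rankings[[1L]]$column_ids
  for (r in rankings) {
    if (length(r$column_ids) != length(ids) || !all(r$column_ids == ids))
      stop("inconsistent column sets across selector rankings")
  }
  p <- length(ids)
  if (k < 1L || k > p) stop("k must be between 1 and the number of columns")
  ranks <- vapply(rankings, function(r) as.numeric(r$rank), numeric(p))
  mean_rank <- rowMeans(ranks)
  ord <- order(mean_rank, seq_len(p))
  tab <- data.frame(column_id = ids, mean_rank = mean_rank,
                    stringsAsFactors = FALSE)
  for (r in rankings) tab[[paste0("score_", r$selector)]] <- unname(r$score)
  tab$selected <- seq_len(p) %in% ord[seq_len(k)]
  list(selected = ids[ord[seq_len(k)]],
       mean_rank = setNames(mean_rank, ids),
       order = ord,
       table = tab[ord, ])
}

#' Run all three selectors and keep the consensus top-k
#'
#' @param X records x features matrix (normalised internally)
#' @param y labels in {0, 1}
#' @param k columns to keep (default 30)
#' @param n_trees,seed,max_depth forwarded to
#'   \code{\link{extraTreesImportance}}
#' @param shap_rows optional row subset for the SHAP pass
#' @return as \code{\link{aggregateAndSelect}}, plus the individual rankings
#' @export
selectFeatures <- function(X, y, k = 30L, n_trees = 100L, seed = 1L,
                           max_depth = 10L, shap_rows = NULL) {
  Xs <- normaliseFeatures(X)
  uni <- univariateScores(Xs, y)
  trees <- extraTreesImportance(Xs, y, n_trees = n_trees, seed = seed,
                                max_depth = max_depth)
  shap <- shapImportance(trees, Xs, rows = shap_rows)
  sel <- aggregateAndSelect(list(uni, trees, shap), k = k)
  sel$rankings <- list(univariate = uni, extra_trees = trees, shap = shap)
  sel
}
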