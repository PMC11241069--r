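# Homogeneous graph construction from scalar node attention scores.
#
# Nodes are inserted in ascending score order within each class. Same-class
# groups keep a running mean attention score; an incoming node links to the
# members of every group whose running mean lies within node_threshold of
# its own score (groups visited in ascending running-mean order, full groups
# skipped), joins the first admitting group, and otherwise seeds a new
# singleton group. One parameter, node_connections, caps both the number of
# links a node may create and the group size.

#' Assign provisional classes from attention scores
#'
#' Training nodes keep their true label. Held-out nodes receive the label of
#' the nearer training-score class centroid (one-dimensional
#' nearest-centroid; ties go to class 0). With
#' \code{method = "true_labels"} every node keeps its true label (label
#' leakage for evaluation nodes — use only to reproduce that behaviour
#' deliberately).
#'
#' @param scores numeric attention score per node
#' @param train_idx indices of training nodes
#' @param train_labels labels in {0, 1} for the training nodes
#' @param method "centroid" (default) or "true_labels"
#' @param all_labels full label vector, required for "true_labels"
#' @return integer vector of provisional classes, one per node
#' @export
assignProvisionalClass <- function(scores, train_idx, train_labels,
                                   method = c("centroid", "true_labels"),
                                   all_labels = NULL) {
  method <- match.arg(method)
  n <- length(scores)
  if (method == "true_labels") {
    if (is.null(all_labels) || length(all_labels) != n)
      stop("method 'true_labels' needs the full label vector")
    return(as.integer(all_labels))
  }
  stopifnot(length(train_idx) >= 1L, length(train_idx) == length(train_labels))
  train_labels <- as.integer(train_labels)
  if (length(unique(train_labels)) < 2L)
    stop("training labels must contain both classes")
  c0 <- mean(scores[train_idx][train_labels == 0L])
  c1 <- mean(scores[train_idx][train_labels == 1L])
  cls <- ifelse(abs(scores - c1) < abs(scores - c0), 1L, 0L)  # tie -> 0
  cls[train_idx] <- train_labels
  as.integer(cls)
}

# Insert one node into the class-conditional group registry.
# groups: list of list(cls, members, mean, created); returns new edges
# (to-member indices), their score gaps, and the updated registry.
insert_node <- function(node_idx, score, cls, groups, node_threshold,
                        node_connections) {
  same <- which(vapply(groups, function(g) g$cls == cls, logical(1L)))
  if (length(same)) {
    means <- vapply(groups[same], `[[`, numeric(1L), "mean")
    created <- vapply(groups[same], `[[`, numeric(1L), "created")
    same <- same[order(means, created)]
  }
  links <- integer(0L)
  gaps <- numeric(0L)
  joined <- FALSE
  for (gi in same) {
    if (length(links) >= node_connections) break
    g <- groups[[gi]]
    if (length(g$members) >= node_connections) next  # group at capacity
    gap <- abs(score - g$mean)
    if (gap > node_threshold) next
    room <- node_connections - length(links)
    take <- head(g$members, room)
    links <- c(links, take)
    gaps <- c(gaps, rep(gap, length(take)))
    if (!joined) {
      g$members <- c(g$members, node_idx)
      g$sum <- g$sum + score
      g$mean <- g$sum / length(g$members)
      groups[[gi]] <- g
      joined <- TRUE
    }
  }
  if (!joined) {
    groups[[length(groups) + 1L]] <- list(
      cls = cls, members = node_idx, sum = score, mean = score,
      created = length(groups) + 1L)
  }
  list(links = links, gaps = gaps, groups = groups)
}

#' Link one node into an existing group registry
#'
#' Single-step version of the insertion procedure used by
#' \code{\link{buildGraph}}, exposed for inspection: given a node's score and
#' class and the current registry of class-conditional groups, returns the
#' edges the node creates, their score gaps, and the updated registry.
#'
#' @param score,cls the node's attention score and class (0/1)
#' @param groups group registry (possibly empty list)
#' @param node_idx index the node will carry in the edge list
#' @param node_threshold maximum |score - group running mean| to join
#' @param node_connections cap on links per node and on group size
#' @export
getNodeAdjacents <- function(score, cls, groups = list(), node_idx = 1L,
                             node_threshold = 200, node_connections = 5L) {
  stopifnot(node_threshold >= 0, node_connections >= 0L)
  insert_node(node_idx, score, as.integer(cls), groups, node_threshold,
              node_connections)
}

#' Build the homogeneous patient graph
#'
#' Nodes are processed per class in ascending attention-score order (ties by
#' record id). Directed insertion edges (new node to existing member) are
#' recorded together with the score gap at link time; by default the edge
#' list is also symmetrised for message passing when accessed via
#' \code{\link{edgeList}}.
#'
#' @param features n x k node feature matrix
#' @param labels provisional or true classes in {0, 1}
#' @param scores node attention scores
#' @param record_ids node identifiers (default R1..Rn)
#' @param node_threshold maximum score gap for joining a group (default 200)
#' @param node_connections per-node link cap = group size cap (default 5)
#' @param symmetrise store the graph flagged for symmetrised access
#' @return a \linkS4class{ReportGraph}
#' @export
buildGraph <- function(features, labels, scores, record_ids = NULL,
                       node_threshold = 200, node_connections = 5L,
                       symmetrise = TRUE) {
  stopifnot(is.matrix(features), nrow(features) >= 1L,
            nrow(features) == length(labels),
            nrow(features) == length(scores),
            node_threshold >= 0, node_connections >= 0L)
  n <- nrow(features)
  labels <- as.integer(labels)
  if (is.null(record_ids)) record_ids <- paste0("R", seq_len(n))
  from <- to <- integer(0L)
  gaps <- numeric(0L)
  groups <- list()
  for (cls in c(0L, 1L)) {
    idx <- which(labels == cls)
    if (!length(idx)) next
    idx <- idx[order(scores[idx], record_ids[idx])]
    for (i in idx) {
      res <- insert_node(i, scores[i], cls, groups, node_threshold,
                         node_connections)
      groups <- res$groups
      if (length(res$links)) {
        from <- c(from, rep(i, length(res$links)))
        to <- c(to, res$links)
        gaps <- c(gaps, res$gaps)
      }
    }
  }
  edges <- cbind(from = from, to = to)
  storage.mode(edges) <- "integer"
  new("ReportGraph", features = features, labels = labels,
      scores = as.numeric(scores), recordIds = record_ids, edges = edges,
      edgeGap = gaps, groups = groups,
      params = list(node_threshold = node_threshold,
                    node_connections = as.integer(node_connections),
                    symmetrise = symmetrise))
}

#' Sweep the node threshold and pick the best value
#'
#' Evaluates a callback at every candidate threshold and returns the
#' candidate maximising the callback's metric (ties resolved towards the
#' smallest threshold) together with the full table.
#'
#' @param candidates numeric vector of thresholds (non-empty)
#' @param eval_fn function(threshold) returning a scalar metric
#'   (larger = better)
#' @return list with \code{best} and \code{table}
#' @export
thresholdSweep <- function(candidates, eval_fn) {
  if (length(candidates) < 1L) stop("at least one candidate threshold needed")
  candidates <- sort(candidates)
  metric <- vapply(candidates, function(th) as.numeric(eval_fn(th)),
                   numeric(1L))
  best <- candidates[which.max(metric)]  # which.max takes the first maximum
  list(best = best, table = data.frame(threshold = candidates,
                                       metric = metric))
}
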