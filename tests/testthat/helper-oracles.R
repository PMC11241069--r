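# Independent brute-force oracles used across the suite. Each one is a
# plain-loop or enumeration re-statement of the quantity it checks and never
# calls the implementation it is compared against.

# column means by explicit elementwise loops
oracle_col_means <- function(m, rows = seq_len(nrow(m))) {
  out <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    s <- 0
    for (i in rows) s <- s + m[i, j]
    out[j] <- s / length(rows)
  }
  out
}

# elementwise mean across the first dimension of a 3-way array
oracle_head_mean <- function(a) {
  H <- dim(a)[1L]
  out <- matrix(0, dim(a)[2L], dim(a)[3L])
  for (i in seq_len(dim(a)[2L])) for (j in seq_len(dim(a)[3L])) {
    s <- 0
    for (h in seq_len(H)) s <- s + a[h, i, j]
    out[i, j] <- s / H
  }
  out
}

# masked sum of the layer/head-averaged attention stack
oracle_masked_sum <- function(stack, pad_mask) {
  d <- dim(stack)
  real <- which(pad_mask)
  total <- 0
  for (i in real) for (j in real) {
    s <- 0
    for (l in seq_len(d[1L])) for (h in seq_len(d[2L])) s <- s + stack[l, h, i, j]
    total <- total + s / (d[1L] * d[2L])
  }
  total
}

# AUC by exhaustive concordant-pair counting (ties count half)
oracle_pair_auc <- function(y, p) {
  pos <- which(y == 1L)
  neg <- which(y == 0L)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + if (p[i] > p[j]) 1 else if (p[i] == p[j]) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# per-node neighbour aggregation by explicit loops over the edge list
oracle_aggregate <- function(M, edges, n, mode) {
  out <- matrix(0, n, ncol(M))
  for (v in seq_len(n)) {
    src <- edges[edges[, 2L] == v, 1L]
    if (!length(src)) next
    sub <- M[src, , drop = FALSE]
    out[v, ] <- switch(mode,
      sum = apply(sub, 2L, sum),
      mean = apply(sub, 2L, mean),
      max = apply(sub, 2L, max))
  }
  out
}

# literal step-through of the grouping pseudo-code: per class, sort nodes by
# ascending score; each node scans groups in ascending running-mean order,
# links to members of admitting groups (gap <= threshold, group not full)
# until its link budget is spent, joins the first admitting group, else
# seeds a new group
oracle_build_edges <- function(scores, labels, ids, threshold, cap) {
  groups <- list()
  edges <- NULL
  for (cls in c(0L, 1L)) {
    idx <- which(labels == cls)
    idx <- idx[order(scores[idx], ids[idx])]
    for (i in idx) {
      cand <- Filter(function(g) g$cls == cls, groups)
      keys <- vapply(groups, function(g) g$cls == cls, logical(1L))
      ord <- which(keys)
      if (length(ord)) {
        mm <- vapply(groups[ord], function(g) g$mean, numeric(1L))
        cr <- vapply(groups[ord], function(g) g$created, numeric(1L))
        ord <- ord[order(mm, cr)]
      }
      links <- integer(0L)
      joined <- FALSE
      for (gi in ord) {
        if (length(links) >= cap) break
        g <- groups[[gi]]
        if (length(g$members) >= cap) next
        if (abs(scores[i] - g$mean) > threshold) next
        take <- g$members[seq_len(min(length(g$members), cap - length(links)))]
        links <- c(links, take)
        if (!joined) {
          g$members <- c(g$members, i)
          g$mean <- mean(scores[g$members])
          groups[[gi]] <- g
          joined <- TRUE
        }
      }
      if (!joined)
        groups[[length(groups) + 1L]] <- list(cls = cls, members = i,
                                              mean = scores[i],
                                              created = length(groups) + 1L)
      if (length(links)) edges <- rbind(edges, cbind(i, links))
    }
  }
  if (is.null(edges)) matrix(integer(0L), 0L, 2L) else unname(edges)
}

# exact Shapley values for one tree ensemble by coalition enumeration, with
# path-dependent (cover-weighted) conditional expectations
oracle_tree_shapley <- function(forest, xrow, p) {
  exp_f <- function(S, node, off) {
    if (forest$left[off + node] < 0L) return(forest$value[off + node])
    f <- forest$feature[off + node] + 1L
    l <- forest$left[off + node] + 1L
    r <- forest$right[off + node] + 1L
    if (f %in% S) {
      nxt <- if (xrow[f] <= forest$threshold[off + node]) l else r
      exp_f(S, nxt, off)
    } else {
      (forest$cover[off + l] * exp_f(S, l, off) +
       forest$cover[off + r] * exp_f(S, r, off)) / forest$cover[off + node]
    }
  }
  n_trees <- length(forest$tree_start) - 1L
  phi <- numeric(p)
  subsets <- lapply(0:(2^p - 1L),
                    function(m) which(bitwAnd(m, 2^(0:(p - 1L))) > 0))
  for (t in seq_len(n_trees)) {
    off <- forest$tree_start[t]
    for (j in seq_len(p)) for (S in subsets) {
      if (j %in% S) next
      s <- length(S)
      w <- factorial(s) * factorial(p - s - 1L) / factorial(p)
      phi[j] <- phi[j] +
        w * (exp_f(c(S, j), 1L, off) - exp_f(S, 1L, off)) / n_trees
    }
  }
  phi
}

gelu_helper <- function(x) x * pnorm(x)

with_seed_helper <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

make_record <- function(id, text) list(record_id = id, text = text)

# small deterministic corpus for encoder tests
tiny_records <- function(n = 4L, words = 6L) {
  lapply(seq_len(n), function(i)
    make_record(sprintf("MR%03d", i),
                paste(rep(c("ductal", "carcinoma", "margins", "benign"),
                          length.out = words + i), collapse = " ")))
}
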