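test_that("FFN block: zero map, no-op dropout, hand-computed GELU pass", {
  # zero dense weights -> GELU(0) = 0 regardless of input
  blk <- list(list(gamma = rep(1, 2), beta = rep(0, 2),
                   run_mean = rep(0, 2), run_var = rep(1, 2),
                   W = matrix(0, 2, 2), b = rep(0, 2)))
  x <- matrix(c(1, -2, 3, 4), 2L, 2L)
  out <- ffnBlockForward(x, blk, dropout = 0, training = FALSE)
  expect_equal(out$out, matrix(0, 2L, 2L))

  # dropout rate 0: output independent of the RNG state
  blk2 <- with_seed_helper(4L, TextGraphNet:::init_ffn_block(c(2L, 3L)))
  set.seed(1); o1 <- ffnBlockForward(x, blk2, dropout = 0, training = TRUE)
  set.seed(2); o2 <- ffnBlockForward(x, blk2, dropout = 0, training = TRUE)
  expect_identical(o1$out, o2$out)

  # 1x2 input through hand-set 2x2 weights, inference-mode normalisation
  W <- matrix(c(1, 0, 1, -1), 2L, 2L)
  blk3 <- list(list(gamma = rep(1, 2), beta = rep(0, 2),
                    run_mean = rep(0, 2), run_var = rep(1, 2),
                    W = W, b = c(0.5, 0)))
  xin <- matrix(c(2, 1), 1L, 2L)
  eps <- 1e-5
  xhat <- c(2, 1) / sqrt(1 + eps)
  lin <- c(xhat %*% W) + c(0.5, 0)
  expect_equal(
    ffnBlockForward(xin, blk3, training = FALSE)$out,
    matrix(lin * pnorm(lin), 1L, 2L), tolerance = 1e-12)
})

test_that("graph convolution: isolated nodes, sum/mean scaling, max oracle", {
  params <- list(Wm = diag(2), bm = c(0, 0), Wu = rbind(diag(2), diag(2)),
                 bu = c(0, 0), Ws = NULL)
  H <- rbind(c(1, 2), c(3, 4), c(-1, 0.5))
  no_edges <- matrix(integer(0L), 0L, 2L)
  out0 <- graphConvForward(H, no_edges, params, "sum")$out
  # no edges: output is a per-row function of the node's own state only
  own <- gelu_helper(H) + H  # update reduces to GELU(H) + skip
  expect_equal(out0, own, tolerance = 1e-12)

  # star: hub 1 with 4 identical leaves; sum message = 4 x mean message
  Hs <- rbind(c(0, 0), matrix(rep(c(1, 2), 4L), 4L, 2L, byrow = TRUE))
  star <- cbind(from = 2:5, to = rep(1L, 4L))
  agg_sum <- TextGraphNet:::aggregate_messages(Hs, star, 5L, "sum")$agg
  agg_mean <- TextGraphNet:::aggregate_messages(Hs, star, 5L, "mean")$agg
  expect_equal(agg_sum[1L, ], 4 * agg_mean[1L, ])
  expect_equal(agg_sum[1L, ], c(4, 8))

  # 3-node path, identity transforms, max aggregation vs per-node loop oracle
  Hp <- rbind(c(5, -1), c(0, 2), c(3, 7))
  path <- cbind(from = c(1L, 3L, 2L, 2L), to = c(2L, 2L, 1L, 3L))
  got <- TextGraphNet:::aggregate_messages(Hp, path, 3L, "max")$agg
  expect_equal(got, oracle_aggregate(Hp, path, 3L, "max"))

  expect_error(graphConvForward(H, cbind(1L, 9L), params, "sum"),
               "out of range")
})

test_that("aggregation modes match loop oracles on 100 random graphs", {
  set.seed(77)
  for (rep in 1:100) {
    n <- sample(3:10, 1L)
    w <- sample(2:4, 1L)
    M <- matrix(rnorm(n * w), n, w)
    ne <- sample(0:(2L * n), 1L)
    edges <- if (ne == 0L) matrix(integer(0L), 0L, 2L) else {
      e <- cbind(sample(n, ne, TRUE), sample(n, ne, TRUE))
      e[e[, 1L] != e[, 2L], , drop = FALSE]
    }
    for (mode in c("sum", "mean", "max")) {
      got <- TextGraphNet:::aggregate_messages(M, edges, n, mode)$agg
      expect_equal(got, oracle_aggregate(M, edges, n, mode),
                   tolerance = 1e-10)
    }
  }
})

test_that("sum aggregation equals the dense-adjacency matrix product", {
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(4:20, 1L)
    H <- matrix(rnorm(n * 3L), n, 3L)
    ne <- sample(1:(3L * n), 1L)
    edges <- cbind(sample(n, ne, TRUE), sample(n, ne, TRUE))
    edges <- unique(edges[edges[, 1L] != edges[, 2L], , drop = FALSE])
    A <- matrix(0, n, n)
    A[edges[, c(2L, 1L), drop = FALSE]] <- 1  # A[to, from] = 1
    got <- TextGraphNet:::aggregate_messages(H, edges, n, "sum")$agg
    expect_equal(got, A %*% H, tolerance = 1e-10)
  }
})

test_that("model forward: probability rows, uniform logits, equivariance", {
  set.seed(5)
  n <- 8L; k <- 3L
  X <- matrix(rnorm(n * k), n, k)
  edges <- cbind(from = c(1L, 2L, 3L, 5L), to = c(2L, 3L, 1L, 6L))
  m <- initGraphClassifier(k, c(4L, 4L), seed = 2L)
  probs <- modelForward(m, X, edges)
  expect_true(all(probs >= 0))
  expect_equal(rowSums(probs), rep(1, n), tolerance = 1e-6)

  # zero softmax-head weights -> every row [0.5, 0.5]
  m0 <- m
  m0@params$head$W[] <- 0
  m0@params$head$b[] <- 0
  expect_equal(modelForward(m0, X, edges), matrix(0.5, n, 2L),
               tolerance = 1e-12)

  # permuting nodes and edges consistently permutes the output
  perm <- sample(n)
  inv <- order(perm)
  Xp <- X[perm, , drop = FALSE]
  edgesp <- cbind(from = inv[edges[, 1L]], to = inv[edges[, 2L]])
  probsp <- modelForward(m, Xp, edgesp)
  expect_equal(probsp[inv, ], probs, tolerance = 1e-10)
})

test_that("two-node graph model matches a fully hand-computed forward pass", {
  # minimal geometry: 1 feature, 1-layer blocks of width 1, edge 1 -> 2
  m <- initGraphClassifier(1L, c(1L, 1L), ffn_stack_depth = 1L, seed = 1L)
  p <- m@params
  p$pre[[1L]] <- list(gamma = 1, beta = 0, run_mean = 0, run_var = 1,
                      W = matrix(2, 1, 1), b = 0)
  p$gc1 <- list(Wm = matrix(1, 1, 1), bm = 0,
                Wu = matrix(c(1, 1), 2, 1), bu = 0, Ws = NULL)
  p$gc2 <- list(Wm = matrix(0.5, 1, 1), bm = 0,
                Wu = matrix(c(1, -1), 2, 1), bu = 0, Ws = NULL)
  p$post[[1L]] <- list(gamma = 1, beta = 0, run_mean = 0, run_var = 1,
                       W = matrix(1, 1, 1), b = 0)
  p$head <- list(W = matrix(c(1, -1), 1, 2), b = c(0, 0))
  m@params <- p
  X <- matrix(c(1, -1), 2L, 1L)
  edges <- cbind(from = 1L, to = 2L)

  gelu <- function(x) x * pnorm(x)
  eps <- 1e-5
  h <- gelu((X / sqrt(1 + eps)) * 2)              # pre block (inference BN)
  msg1 <- c(0, h[1L])                             # only node 2 hears node 1
  g1 <- gelu(h + msg1) + h                        # Wu = [1;1], skip
  msg2 <- c(0, 0.5 * g1[1L])
  g2 <- gelu(g1 - msg2) + g1                      # Wu = [1;-1]
  hf <- gelu(g2 / sqrt(1 + eps))                  # post block
  logits <- cbind(hf, -hf)
  want <- exp(logits) / rowSums(exp(logits))
  expect_equal(unname(modelForward(m, X, edges)), unname(want),
               tolerance = 1e-10)
})

test_that("baseline: uniform logits at zero head, pure skip path, hand pass", {
  set.seed(6)
  X <- matrix(rnorm(10L), 5L, 2L)
  b <- initBaseline(2L, width = 2L, ffn_stack_depth = 1L, seed = 3L)
  probs <- modelForward(b, X)
  expect_equal(rowSums(probs), rep(1, 5L), tolerance = 1e-6)

  b0 <- b
  b0@params$head$W[] <- 0; b0@params$head$b[] <- 0
  expect_equal(modelForward(b0, X), matrix(0.5, 5L, 2L))

  # zeroing the inner blocks leaves the pure skip path: logits = head(X)
  bz <- b
  for (t in seq_along(bz@params$iters)) {
    for (blk in c("f1", "f2")) {
      for (l in seq_along(bz@params$iters[[t]][[blk]])) {
        bz@params$iters[[t]][[blk]][[l]]$W[] <- 0
        bz@params$iters[[t]][[blk]][[l]]$b[] <- 0
      }
    }
  }
  logits <- X %*% bz@params$head$W +
    matrix(bz@params$head$b, 5L, 2L, byrow = TRUE)
  want <- exp(logits) / rowSums(exp(logits))
  expect_equal(modelForward(bz, X), want, tolerance = 1e-10)

  # single record, widths 2 -> 2, hand-set weights, one iteration
  b1 <- initBaseline(2L, width = 2L, ffn_stack_depth = 1L,
                     n_iterations = 1L, seed = 4L)
  p <- b1@params
  p$iters[[1L]]$f1[[1L]] <- list(gamma = c(1, 1), beta = c(0, 0),
                                 run_mean = c(0, 0), run_var = c(1, 1),
                                 W = diag(2), b = c(0, 0))
  p$iters[[1L]]$f2[[1L]] <- list(gamma = c(1, 1), beta = c(0, 0),
                                 run_mean = c(0, 0), run_var = c(1, 1),
                                 W = matrix(c(1, 1, 0, 2), 2, 2), b = c(1, 0))
  p$head <- list(W = diag(2), b = c(0, 0))
  b1@params <- p
  x <- matrix(c(0.5, -1), 1L, 2L)
  eps <- 1e-5
  gelu <- function(z) z * pnorm(z)
  h1 <- gelu(c(x) / sqrt(1 + eps))
  h2 <- gelu(c(h1 %*% matrix(c(1, 1, 0, 2), 2, 2) / sqrt(1 + eps)) + c(1, 0))
  logits <- c(x) + h2  # identity skip + block output, identity head
  want <- exp(logits) / sum(exp(logits))
  expect_equal(c(modelForward(b1, x)), want, tolerance = 1e-10)
})

test_that("analytic gradients match central finite differences", {
  set.seed(42)
  n <- 7L; k <- 3L
  X <- matrix(rnorm(n * k), n, k)
  y <- rbinom(n, 1L, 0.5)
  edges <- cbind(from = c(1L, 2L, 3L, 4L, 5L, 2L, 7L),
                 to = c(2L, 1L, 4L, 3L, 6L, 5L, 1L))
  eps <- 1e-6
  check_paths <- function(model, kind, edges, paths) {
    g <- TextGraphNet:::model_grad(model@params, model@hyper, kind, X, edges,
                                   y, seq_len(n), training = TRUE)
    worst <- 0
    for (pth in paths) {
      par <- model@params
      for (s in pth) par <- par[[s]]
      gr <- g$grads
      for (s in pth) gr <- gr[[s]]
      if (is.null(par)) next
      for (ii in seq_len(min(3L, length(par)))) {
        bump <- function(d) {
          pp <- model@params
          expr <- "pp"
          for (s in pth) expr <- if (is.character(s))
            sprintf('%s[["%s"]]', expr, s) else sprintf("%s[[%d]]", expr, s)
          eval(parse(text = sprintf("%s[ii] <- %s[ii] + d", expr, expr)))
          pp
        }
        fd <- (TextGraphNet:::model_grad(bump(eps), model@hyper, kind, X,
                                         edges, y, seq_len(n), TRUE)$loss -
               TextGraphNet:::model_grad(bump(-eps), model@hyper, kind, X,
                                         edges, y, seq_len(n), TRUE)$loss) /
          (2 * eps)
        worst <- max(worst, abs(fd - gr[ii]) / max(1e-8, abs(fd) + abs(gr[ii])))
      }
    }
    worst
  }
  for (agg in c("sum", "mean", "max")) {
    m <- initGraphClassifier(k, c(4L, 5L), dropout = 0,
                             ffn_stack_depth = 2L, aggregation = agg,
                             seed = 3L)
    worst <- check_paths(m, "graph", edges,
                         list(c("pre", 1L, "W"), c("pre", 1L, "gamma"),
                              c("gc1", "Wm"), c("gc1", "Wu"),
                              c("gc2", "Ws"), c("post", 1L, "W"),
                              c("head", "W"), c("head", "b")))
    expect_lt(worst, 1e-5)
  }
  bl <- initBaseline(k, width = 5L, dropout = 0, ffn_stack_depth = 2L,
                     n_iterations = 3L, seed = 2L)
  worst <- check_paths(bl, "baseline", matrix(integer(0L), 0L, 2L),
                       list(c("iters", 1L, "proj"),
                            c("iters", 1L, "f1", 1L, "W"),
                            c("iters", 2L, "f2", 2L, "gamma"),
                            c("head", "W")))
  expect_lt(worst, 1e-5)
})
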