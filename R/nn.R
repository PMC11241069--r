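# Hand-written dense/batch-norm/dropout/GELU/graph-convolution primitives
# with exact backward passes (verified against finite differences in the
# test suite). All parameters live in nested lists of numeric arrays so a
# single Adam implementation can walk them.

gelu <- function(x) x * pnorm(x)
dgelu <- function(x) pnorm(x) + x * dnorm(x)

bn_forward <- function(x, layer, training, eps = 1e-5, momentum = 0.9) {
  if (training) {
    mu <- colMeans(x)
    xc <- sweep(x, 2L, mu)
    v <- colMeans(xc^2)  # population variance over the batch
    layer$run_mean <- momentum * layer$run_mean + (1 - momentum) * mu
    layer$run_var <- momentum * layer$run_var + (1 - momentum) * v
  } else {
    mu <- layer$run_mean
    v <- layer$run_var
    xc <- sweep(x, 2L, mu)
  }
  inv_std <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, inv_std, `*`)
  out <- sweep(sweep(xhat, 2L, layer$gamma, `*`), 2L, layer$beta, `+`)
  list(out = out, layer = layer,
       cache = list(xhat = xhat, inv_std = inv_std, gamma = layer$gamma,
                    training = training))
}

bn_backward <- function(dout, cache) {
  xhat <- cache$xhat
  n <- nrow(dout)
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2L, cache$gamma, `*`)
  if (cache$training) {
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * xhat)
    dx <- sweep(dxhat * n, 2L, s1) - sweep(xhat, 2L, s2, `*`)
    dx <- sweep(dx, 2L, cache$inv_std / n, `*`)
  } else {
    dx <- sweep(dxhat, 2L, cache$inv_std, `*`)
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

dropout_forward <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(out = x, mask = NULL))
  mask <- matrix(
    (runif(length(x)) >= rate) / (1 - rate), nrow(x), ncol(x))
  list(out = x * mask, mask = mask)
}

dense_forward <- function(x, W, b) {
  list(out = sweep(x %*% W, 2L, b, `+`), x = x)
}

dense_backward <- function(dout, cache, W) {
  list(dx = dout %*% t(W), dW = crossprod(cache$x, dout),
       db = colSums(dout))
}

init_dense <- function(w_in, w_out) {
  list(W = matrix(rnorm(w_in * w_out, sd = sqrt(2 / w_in)), w_in, w_out),
       b = numeric(w_out))
}

init_ffn_layer <- function(w_in, w_out) {
  c(list(gamma = rep(1, w_in), beta = numeric(w_in),
         run_mean = numeric(w_in), run_var = rep(1, w_in)),
    init_dense(w_in, w_out))
}

init_ffn_block <- function(widths) {
  # widths: length depth+1 chain of layer widths
  lapply(seq_len(length(widths) - 1L), function(i)
    init_ffn_layer(widths[i], widths[i + 1L]))
}

#' Feedforward block forward pass
#'
#' Applies, per stacked layer: batch normalisation, dropout (inactive unless
#' \code{training}), dense transform, GELU activation.
#'
#' @param x n x width input matrix
#' @param block block parameter list (see \code{\link{initGraphClassifier}})
#' @param dropout dropout rate in [0, 1)
#' @param training logical; enables batch statistics and dropout
#' @return list with \code{out}, updated \code{block} (running statistics)
#'   and backward \code{cache}
#' @export
ffnBlockForward <- function(x, block, dropout = 0, training = FALSE) {
  caches <- vector("list", length(block))
  for (i in seq_along(block)) {
    layer <- block[[i]]
    bn <- bn_forward(x, layer, training)
    block[[i]] <- bn$layer
    dp <- dropout_forward(bn$out, dropout, training)
    dn <- dense_forward(dp$out, layer$W, layer$b)
    caches[[i]] <- list(bn = bn$cache, mask = dp$mask, dense = dn,
                        lin = dn$out)
    x <- gelu(dn$out)
  }
  list(out = x, block = block, cache = caches)
}

ffn_block_backward <- function(dout, block, cache) {
  grads <- vector("list", length(block))
  for (i in rev(seq_along(block))) {
    cc <- cache[[i]]
    dlin <- dout * dgelu(cc$lin)
    dn <- dense_backward(dlin, cc$dense, block[[i]]$W)
    dd <- if (is.null(cc$mask)) dn$dx else dn$dx * cc$mask
    bb <- bn_backward(dd, cc$bn)
    grads[[i]] <- list(gamma = bb$dgamma, beta = bb$dbeta,
                       run_mean = NULL, run_var = NULL,
                       W = dn$dW, b = dn$db)
    dout <- bb$dx
  }
  list(dx = dout, grads = grads)
}

init_graph_conv <- function(w_in, w_out) {
  msg <- init_dense(w_in, w_out)
  upd <- init_dense(w_in + w_out, w_out)
  list(Wm = msg$W, bm = msg$b, Wu = upd$W, bu = upd$b,
       Ws = if (w_in == w_out) NULL
            else matrix(rnorm(w_in * w_out, sd = sqrt(1 / w_in)), w_in, w_out))
}

aggregate_messages <- function(M, edges, n, mode) {
  w <- ncol(M)
  agg <- matrix(0, n, w)
  argmax <- NULL
  if (nrow(edges) > 0L) {
    if (mode %in% c("sum", "mean")) {
      rs <- rowsum(M[edges[, 1L], , drop = FALSE], group = edges[, 2L])
      tgt <- as.integer(rownames(rs))
      agg[tgt, ] <- rs
      if (mode == "mean") {
        deg <- tabulate(edges[, 2L], nbins = n)
        agg[tgt, ] <- agg[tgt, , drop = FALSE] / deg[tgt]
      }
    } else {  # max; isolated nodes keep the zero vector by convention
      argmax <- matrix(0L, n, w)
      by_target <- split(seq_len(nrow(edges)), edges[, 2L])
      for (tg in names(by_target)) {
        es <- by_target[[tg]]
        sub <- M[edges[es, 1L], , drop = FALSE]
        wm <- max.col(t(sub), ties.method = "first")
        t_i <- as.integer(tg)
        agg[t_i, ] <- sub[cbind(wm, seq_len(w))]
        argmax[t_i, ] <- es[wm]
      }
    }
  }
  list(agg = agg, argmax = argmax)
}

#' Graph convolution forward pass
#'
#' Per node: transform neighbour states (linear message map), aggregate the
#' messages arriving along incoming edges by \code{mode} (isolated nodes get
#' a zero message), update via GELU(dense([own state, aggregated message]))
#' and add a skip connection (identity, or a dense projection when widths
#' differ).
#'
#' @param H n x w_in node state matrix
#' @param edges integer matrix (from, to); messages flow from -> to
#' @param params graph-conv parameter list
#' @param mode "sum", "mean" or "max"
#' @return list with \code{out} and backward \code{cache}
#' @export
graphConvForward <- function(H, edges, params, mode = c("sum", "mean", "max")) {
  mode <- match.arg(mode)
  n <- nrow(H)
  if (nrow(edges) > 0L &&
      (max(edges) > n || min(edges) < 1L))
    stop("edge endpoints out of range")
  Mn <- dense_forward(H, params$Wm, params$bm)
  ag <- aggregate_messages(Mn$out, edges, n, mode)
  cat_in <- cbind(H, ag$agg)
  U <- dense_forward(cat_in, params$Wu, params$bu)
  A <- gelu(U$out)
  skip <- if (is.null(params$Ws)) H else H %*% params$Ws
  list(out = A + skip,
       cache = list(H = H, M = Mn$out, agg = ag$agg, argmax = ag$argmax,
                    cat = cat_in, U = U$out, edges = edges, mode = mode))
}

graph_conv_backward <- function(dout, params, cache) {
  H <- cache$H
  n <- nrow(H)
  w_in <- ncol(H)
  w_msg <- ncol(cache$M)
  edges <- cache$edges
  dU <- dout * dgelu(cache$U)
  dWu <- crossprod(cache$cat, dU)
  dbu <- colSums(dU)
  dcat <- dU %*% t(params$Wu)
  dH <- dcat[, seq_len(w_in), drop = FALSE]
  dagg <- dcat[, w_in + seq_len(w_msg), drop = FALSE]
  dWs <- NULL
  if (is.null(params$Ws)) {
    dH <- dH + dout
  } else {
    dWs <- crossprod(H, dout)
    dH <- dH + dout %*% t(params$Ws)
  }
  # scatter the aggregated-message gradient back onto per-node messages
  dM <- matrix(0, n, w_msg)
  if (nrow(edges) > 0L) {
    if (cache$mode == "sum") {
      dEdge <- dagg[edges[, 2L], , drop = FALSE]
    } else if (cache$mode == "mean") {
      deg <- tabulate(edges[, 2L], nbins = n)
      dEdge <- dagg[edges[, 2L], , drop = FALSE] / deg[edges[, 2L]]
    } else {
      dEdge <- matrix(0, nrow(edges), w_msg)
      nz <- which(cache$argmax > 0L, arr.ind = TRUE)
      if (nrow(nz)) {
        e_idx <- cache$argmax[nz]
        dEdge[cbind(e_idx, nz[, 2L])] <- dagg[nz]
      }
    }
    rs <- rowsum(dEdge, group = edges[, 1L])
    dM[as.integer(rownames(rs)), ] <- rs
  }
  dWm <- crossprod(H, dM)
  dbm <- colSums(dM)
  dH <- dH + dM %*% t(params$Wm)
  list(dx = dH,
       grads = list(Wm = dWm, bm = dbm, Wu = dWu, bu = dbu, Ws = dWs))
}

# --- parameter-tree utilities (nested lists of numeric arrays) -------------

tree_map <- function(f, a) {
  if (is.null(a)) return(NULL)
  if (is.list(a)) return(lapply(a, tree_map, f = f))
  f(a)
}

tree_map2 <- function(f, a, b) {
  if (is.null(a)) return(NULL)
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    return(out)
  }
  if (is.null(b)) return(a)  # no gradient (e.g. running statistics)
  f(a, b)
}

adam_init <- function(params) {
  list(m = tree_map(function(x) x * 0, params),
       v = tree_map(function(x) x * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  # guard: parameters without gradients (running stats) stay untouched
  params <- tree_map2(function(p, u) p - u, params, upd)
  list(params = params, state = state)
}

# zero-gradient skeleton so Adam state lines up with params even for
# parameters a given backward pass does not touch (running stats)
zero_like <- function(params) tree_map(function(x) x * 0, params)
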