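# The two-class node classifier: feedforward pre-processing block, two graph
# convolution layers with sum/mean/max aggregation and skip connections,
# feedforward post-processing block, softmax head — plus the skip-connected
# feedforward baseline (two FFN blocks joined by skip connections, iterated
# four times).

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Initialise the graph node classifier
#'
#' @param input_width number of node features k
#' @param hidden_units widths of the two graph convolution layers
#'   (default c(34, 34))
#' @param dropout dropout rate (default 0.2)
#' @param ffn_stack_depth stacked layers per feedforward block (default 3)
#' @param aggregation neighbour aggregation: "sum", "mean" or "max"
#' @param seed weight initialisation seed
#' @return an untrained \linkS4class{GraphClassifier}
#' @export
initGraphClassifier <- function(input_width, hidden_units = c(34L, 34L),
                                dropout = 0.2, ffn_stack_depth = 3L,
                                aggregation = "sum", seed = 1L) {
  u1 <- hidden_units[1L]; u2 <- hidden_units[2L]
  params <- with_local_seed(seed, list(
    pre = init_ffn_block(c(input_width, rep(u1, ffn_stack_depth))),
    gc1 = init_graph_conv(u1, u1),
    gc2 = init_graph_conv(u1, u2),
    post = init_ffn_block(rep(u2, ffn_stack_depth + 1L)),
    head = init_dense(u2, 2L)
  ))
  new("GraphClassifier", params = params, kind = "graph",
      hyper = list(input_width = as.integer(input_width),
                   hidden_units = as.integer(hidden_units),
                   dropout = dropout,
                   ffn_stack_depth = as.integer(ffn_stack_depth),
                   aggregation = aggregation, seed = as.integer(seed)))
}

#' Initialise the skip-connected feedforward baseline
#'
#' Two feedforward blocks (batch norm, dropout, dense + GELU per stacked
#' layer) joined by a skip connection; the pair is iterated four times with
#' unshared weights, then a softmax head produces class probabilities.
#'
#' @param input_width number of features
#' @param width hidden width (default 34)
#' @param dropout dropout rate
#' @param ffn_stack_depth stacked layers per block
#' @param n_iterations repetitions of the skip-connected pair (default 4)
#' @param seed initialisation seed
#' @return an untrained \linkS4class{GraphClassifier} of kind "baseline"
#' @export
initBaseline <- function(input_width, width = 34L, dropout = 0.2,
                         ffn_stack_depth = 3L, n_iterations = 4L,
                         seed = 1L) {
  params <- with_local_seed(seed, {
    iters <- vector("list", n_iterations)
    w_in <- input_width
    for (t in seq_len(n_iterations)) {
      iters[[t]] <- list(
        proj = if (w_in == width) NULL
               else matrix(rnorm(w_in * width, sd = sqrt(1 / w_in)),
                           w_in, width),
        f1 = init_ffn_block(c(w_in, rep(width, ffn_stack_depth))),
        f2 = init_ffn_block(rep(width, ffn_stack_depth + 1L)))
      w_in <- width
    }
    list(iters = iters, head = init_dense(width, 2L))
  })
  new("GraphClassifier", params = params, kind = "baseline",
      hyper = list(input_width = as.integer(input_width),
                   hidden_units = as.integer(c(width, width)),
                   dropout = dropout,
                   ffn_stack_depth = as.integer(ffn_stack_depth),
                   n_iterations = as.integer(n_iterations),
                   aggregation = "sum", seed = as.integer(seed)))
}

# full forward pass; returns probs, caches and (training) updated params
model_forward_full <- function(params, hyper, kind, X, edges, training) {
  drop <- if (training) hyper$dropout else 0
  cache <- list()
  if (kind == "graph") {
    pre <- ffnBlockForward(X, params$pre, drop, training)
    params$pre <- pre$block
    g1 <- graphConvForward(pre$out, edges, params$gc1, hyper$aggregation)
    g2 <- graphConvForward(g1$out, edges, params$gc2, hyper$aggregation)
    post <- ffnBlockForward(g2$out, params$post, drop, training)
    params$post <- post$block
    hd <- dense_forward(post$out, params$head$W, params$head$b)
    cache <- list(pre = pre$cache, g1 = g1$cache, g2 = g2$cache,
                  post = post$cache, head = hd)
  } else {
    h <- X
    iters_cache <- vector("list", length(params$iters))
    for (t in seq_along(params$iters)) {
      it <- params$iters[[t]]
      f1 <- ffnBlockForward(h, it$f1, drop, training)
      f2 <- ffnBlockForward(f1$out, it$f2, drop, training)
      params$iters[[t]]$f1 <- f1$block
      params$iters[[t]]$f2 <- f2$block
      skip <- if (is.null(it$proj)) h else h %*% it$proj
      iters_cache[[t]] <- list(f1 = f1$cache, f2 = f2$cache, h_in = h)
      h <- skip + f2$out
    }
    hd <- dense_forward(h, params$head$W, params$head$b)
    cache <- list(iters = iters_cache, head = hd)
  }
  list(logits = hd$out, probs = softmax_rows(hd$out), params = params,
       cache = cache)
}

model_backward_full <- function(params, hyper, kind, cache, dlogits) {
  hd <- dense_backward(dlogits, cache$head, params$head$W)
  grads <- list()
  if (kind == "graph") {
    post <- ffn_block_backward(hd$dx, params$post, cache$post)
    g2 <- graph_conv_backward(post$dx, params$gc2, cache$g2)
    g1 <- graph_conv_backward(g2$dx, params$gc1, cache$g1)
    pre <- ffn_block_backward(g1$dx, params$pre, cache$pre)
    grads <- list(pre = pre$grads, gc1 = g1$grads, gc2 = g2$grads,
                  post = post$grads, head = list(W = hd$dW, b = hd$db))
  } else {
    dh <- hd$dx
    it_grads <- vector("list", length(params$iters))
    for (t in rev(seq_along(params$iters))) {
      it <- params$iters[[t]]
      cc <- cache$iters[[t]]
      f2 <- ffn_block_backward(dh, it$f2, cc$f2)
      f1 <- ffn_block_backward(f2$dx, it$f1, cc$f1)
      dproj <- NULL
      dskip_in <- if (is.null(it$proj)) dh else dh %*% t(it$proj)
      if (!is.null(it$proj)) dproj <- crossprod(cc$h_in, dh)
      it_grads[[t]] <- list(proj = dproj, f1 = f1$grads, f2 = f2$grads)
      dh <- dskip_in + f1$dx
    }
    grads <- list(iters = it_grads, head = list(W = hd$dW, b = hd$db))
  }
  grads
}

#' Forward pass through a classifier
#'
#' @param model a \linkS4class{GraphClassifier}
#' @param X n x k feature matrix
#' @param edges edge matrix (from, to); ignored by the baseline
#' @param training enable dropout and batch statistics
#' @return n x 2 matrix of class probabilities (rows sum to 1)
#' @export
modelForward <- function(model, X, edges = NULL, training = FALSE) {
  if (is.null(edges)) edges <- matrix(integer(0L), 0L, 2L)
  fw <- model_forward_full(model@params, model@hyper, model@kind, X, edges,
                           training)
  fw$probs
}

# cross-entropy on integer labels over the masked rows; returns loss,
# gradient w.r.t. logits, and probs
ce_loss <- function(logits, probs, y, mask) {
  nm <- length(mask)
  picked <- probs[cbind(mask, y[mask] + 1L)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dlogits <- matrix(0, nrow(probs), 2L)
  one_hot <- matrix(0, nm, 2L)
  one_hot[cbind(seq_len(nm), y[mask] + 1L)] <- 1
  dlogits[mask, ] <- (probs[mask, , drop = FALSE] - one_hot) / nm
  list(loss = loss, dlogits = dlogits)
}

# one loss + gradient evaluation (the unit the trainer and lr finder share)
model_grad <- function(params, hyper, kind, X, edges, y, mask, training) {
  fw <- model_forward_full(params, hyper, kind, X, edges, training)
  l <- ce_loss(fw$logits, fw$probs, y, mask)
  grads <- model_backward_full(params, hyper, kind, fw$cache, l$dlogits)
  list(loss = l$loss, grads = grads, probs = fw$probs, params = fw$params)
}
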