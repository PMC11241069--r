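# Tokenisation and the deterministic stub transformer encoder.
#
# The encoder contract mirrors what a pretrained transformer returns for one
# report: per-token last-hidden-state embeddings (max_len x d) and an
# attention stack (layers x heads x max_len x max_len) whose non-pad query
# rows are softmax-normalised over non-pad keys. Pad rows/columns carry
# zeros and are excluded from every downstream statistic.

# run code with a deterministic RNG without disturbing the caller's stream
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# stable 31-ary rolling hash of a token string
token_hash <- function(token) {
  h <- 0
  for (code in utf8ToInt(token)) h <- (h * 31 + code) %% 1048573
  h
}

#' Tokenise a report
#'
#' WordPiece-style tokenisation: lowercase, split on non-alphanumeric
#' characters, break very long words into fixed-size pieces, map tokens to
#' hashed vocabulary ids, wrap in start/separator specials, then pad or
#' truncate to \code{max_len}. Ids: 0 = [PAD], 1 = [CLS], 2 = [SEP],
#' content tokens >= 3.
#'
#' @param text raw report string
#' @param max_len padded length (>= 2, to leave room for [CLS] and [SEP])
#' @param keep_blank if FALSE (default), a report that is empty after
#'   normalisation raises a blank-report error
#' @param vocab_size hashed vocabulary size
#' @return a \code{TokenisedReport}: list with \code{token_ids},
#'   \code{pad_mask} (TRUE = real token) and \code{length} (count N of real
#'   tokens, specials included)
#' @export
tokeniseReport <- function(text, max_len = 512L, keep_blank = FALSE,
                           vocab_size = 8192L) {
  stopifnot(is.character(text), length(text) == 1L)
  max_len <- as.integer(max_len)
  if (max_len < 2L) stop("max_len must be >= 2")
  norm <- tolower(text)
  norm <- gsub("[^a-z0-9]+", " ", norm)
  words <- strsplit(trimws(norm), " +")[[1L]]
  words <- words[nzchar(words)]
  if (length(words) == 0L && !keep_blank)
    stop("blank report: no tokens after normalisation")
  # break long words into 8-character pieces (subword fallback)
  if (length(words)) {
    words <- unlist(lapply(words, function(w) {
      if (nchar(w) <= 12L) return(w)
      starts <- seq(1L, nchar(w), by = 8L)
      substring(w, starts, pmin(starts + 7L, nchar(w)))
    }), use.names = FALSE)
  }
  content <- if (length(words))
    3L + vapply(words, token_hash, numeric(1L)) %% (vocab_size - 3L)
  else integer(0L)
  content <- as.integer(content)
  if (length(content) > max_len - 2L) content <- content[seq_len(max_len - 2L)]
  ids <- c(1L, content, 2L)
  n_real <- length(ids)
  ids <- c(ids, rep(0L, max_len - n_real))
  structure(
    list(token_ids = ids,
         pad_mask  = seq_len(max_len) <= n_real,
         length    = n_real),
    class = "TokenisedReport")
}

#' Construct a deterministic stub encoder
#'
#' All weights are a pure function of \code{seed}; encoding the same report
#' twice is bit-identical. Defaults mirror BERT-base geometry (hidden 768,
#' 12 layers, 12 heads).
#'
#' @param hidden_size embedding width d
#' @param n_layers,n_heads attention geometry
#' @param max_len padded sequence length
#' @param seed integer seed
#' @param head_dim rank of the query/key projections
#' @param vocab_size hashed tokeniser vocabulary size
#' @return a \linkS4class{StubEncoder}
#' @export
stubEncoder <- function(hidden_size = 768L, n_layers = 12L, n_heads = 12L,
                        max_len = 512L, seed = 1L, head_dim = 32L,
                        vocab_size = 8192L) {
  hidden_size <- as.integer(hidden_size)
  n_layers <- as.integer(n_layers)
  n_heads <- as.integer(n_heads)
  head_dim <- as.integer(min(head_dim, hidden_size))
  weights <- with_local_seed(as.integer(seed) %% 2147483647L, {
    list(
      Bq = matrix(rnorm(hidden_size * head_dim), hidden_size) /
        sqrt(hidden_size),
      Bk = matrix(rnorm(hidden_size * head_dim), hidden_size) /
        sqrt(hidden_size),
      # per (layer, head) diagonal scales make every head distinct
      sq = array(rnorm(n_layers * n_heads * head_dim) * 2,
                 c(n_layers, n_heads, head_dim)),
      sk = array(rnorm(n_layers * n_heads * head_dim) * 2,
                 c(n_layers, n_heads, head_dim))
    )
  })
  new("StubEncoder", hiddenSize = hidden_size, nLayers = n_layers,
      nHeads = n_heads, maxLen = as.integer(max_len), headDim = head_dim,
      seed = as.integer(seed), vocabSize = as.integer(vocab_size),
      weights = weights)
}

#' Resolve an encoder configuration
#'
#' @param name encoder name; only \code{"stub"} has an offline backend here.
#'   Any other name raises a configuration error naming the encoder.
#' @param ... passed to \code{\link{stubEncoder}}
#' @export
makeEncoder <- function(name = "stub", ...) {
  if (identical(name, "stub")) return(stubEncoder(...))
  stop(sprintf(
    "configuration error: encoder '%s' cannot be loaded (no transformer %s",
    name, "backend is registered); use encoder 'stub'"))
}

# deterministic token embedding, derived from (encoder seed, token id)
stub_token_embedding <- function(enc, id) {
  with_local_seed((enc@seed * 7919 + (id + 1) * 104729) %% 2147483647,
                  rnorm(enc@hiddenSize))
}

# standard sinusoidal positional encodings, rows = positions
sinusoid_positions <- function(n_pos, d) {
  pos <- seq_len(n_pos) - 1L
  j <- seq_len(d) - 1L
  ang <- outer(pos, 10000^(-2 * (j %/% 2) / d))
  out <- ang
  even <- j %% 2L == 0L
  out[, even] <- sin(ang[, even, drop = FALSE])
  out[, !even] <- cos(ang[, !even, drop = FALSE])
  out
}

row_softmax <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

# Core stub forward pass over the N real tokens.
# want_stack: keep the full per-(layer, head) attention matrices; otherwise
# only their running sum is accumulated (memory-light path).
stub_forward <- function(enc, ids_real, want_stack = TRUE) {
  n <- length(ids_real)
  d <- enc@hiddenSize
  X <- t(vapply(ids_real, function(id) stub_token_embedding(enc, id),
                numeric(d)))
  X <- X + sinusoid_positions(n, d)
  L <- enc@nLayers; H <- enc@nHeads; dk <- enc@headDim
  stack <- if (want_stack) array(0, c(L, H, n, n)) else NULL
  accum <- matrix(0, n, n)
  for (l in seq_len(L)) {
    Q0 <- X %*% enc@weights$Bq
    K0 <- X %*% enc@weights$Bk
    layer_mean <- matrix(0, n, n)
    for (h in seq_len(H)) {
      Qh <- sweep(Q0, 2L, enc@weights$sq[l, h, ], `*`)
      Kh <- sweep(K0, 2L, enc@weights$sk[l, h, ], `*`)
      A <- row_softmax(Qh %*% t(Kh) / sqrt(dk))
      if (want_stack) stack[l, h, , ] <- A
      layer_mean <- layer_mean + A
    }
    layer_mean <- layer_mean / H
    accum <- accum + layer_mean * H
    # residual attention-mixing update keeps states bounded
    X <- 0.7 * X + 0.3 * (layer_mean %*% X)
  }
  list(X = X, stack = stack, attn_sum = accum, n = n)
}

#' Encode a tokenised report
#'
#' @param encoder a \linkS4class{StubEncoder}
#' @param tok a \code{TokenisedReport}
#' @param attention keep the full attention stack (set FALSE for the
#'   memory-light path when only pooled outputs are needed)
#' @return an \code{EncoderOutput}: list with \code{token_embeddings}
#'   (max_len x d, pad rows zero), \code{attention_stack}
#'   (layers x heads x max_len x max_len, pad rows/columns zero),
#'   \code{pad_mask} and \code{n_real}
#' @rdname encodeReport
#' @export
setMethod("encodeReport", "StubEncoder", function(encoder, tok,
                                                  attention = TRUE) {
  stopifnot(inherits(tok, "TokenisedReport"))
  if (length(tok$token_ids) != encoder@maxLen)
    stop("tokenised length does not match the encoder max_len")
  if (tok$length < 1L) stop("empty report: no real tokens")
  real <- which(tok$pad_mask)
  fw <- stub_forward(encoder, tok$token_ids[real], want_stack = attention)
  max_len <- encoder@maxLen
  emb <- matrix(0, max_len, encoder@hiddenSize)
  emb[real, ] <- fw$X
  out <- list(token_embeddings = emb, pad_mask = tok$pad_mask,
              n_real = fw$n,
              attn_sum = fw$attn_sum,
              n_layer_heads = encoder@nLayers * encoder@nHeads)
  if (attention) {
    stk <- array(0, c(encoder@nLayers, encoder@nHeads, max_len, max_len))
    stk[, , real, real] <- fw$stack
    out$attention_stack <- stk
  }
  structure(out, class = "EncoderOutput")
})

#' Mean-pooled document embedding
#'
#' Averages the per-token embeddings over the N real (non-pad) tokens:
#' (1/N) * sum of the non-pad rows.
#'
#' @param token_embeddings max_len x d matrix
#' @param pad_mask logical, TRUE = real token
#' @export
meanEmbedding <- function(token_embeddings, pad_mask) {
  stopifnot(nrow(token_embeddings) == length(pad_mask))
  if (!any(pad_mask)) stop("empty report: no non-pad tokens to pool")
  colMeans(token_embeddings[pad_mask, , drop = FALSE])
}

#' Average an attention layer across heads
#'
#' @param layer_attn H x n x n array of per-head attention matrices
#' @return n x n matrix, entry (i, j) = mean over heads of A_ij
#' @export
headMeanAttention <- function(layer_attn) {
  stopifnot(length(dim(layer_attn)) == 3L, dim(layer_attn)[1L] >= 1L)
  apply(layer_attn, c(2L, 3L), mean)
}

#' Scalar attention score for one report (node)
#'
#' The attention stack is averaged over layers and heads, pad rows and
#' columns are removed, and the remaining entries are reduced to a scalar.
#' The default \code{"sum"} keeps the score on the token-count scale (each
#' softmax-normalised non-pad row sums to 1), which is what makes a node
#' grouping threshold of hundreds meaningful; \code{"mean"} and
#' \code{"cls_row_sum"} are alternatives.
#'
#' @param out an \code{EncoderOutput}
#' @param pad_mask logical mask (defaults to the one stored in \code{out})
#' @param method one of "sum", "mean", "cls_row_sum"
#' @return list with \code{score} (non-negative scalar) and the method used
#' @export
nodeAttentionScore <- function(out, pad_mask = out$pad_mask,
                               method = c("sum", "mean", "cls_row_sum")) {
  method <- match.arg(method)
  if (!any(pad_mask)) stop("empty report: no non-pad tokens")
  real <- which(pad_mask)
  if (!is.null(out$attention_stack)) {
    M <- apply(out$attention_stack[, , real, real, drop = FALSE],
               c(3L, 4L), mean)
  } else {
    M <- out$attn_sum / out$n_layer_heads
  }
  score <- switch(method,
    sum = sum(M),
    mean = mean(M),
    cls_row_sum = sum(M[1L, ]))
  list(score = score, method = method)
}

#' Extract the fixed-width feature vector for one report
#'
#' Tokenises the report, encodes it, mean-pools the last hidden state over
#' real tokens, and keeps the first \code{feature_width} components of the
#' pooled embedding (default 767 of the 768-wide hidden state).
#'
#' @param record list with \code{record_id} and \code{text}
#' @param encoder a \linkS4class{StubEncoder}
#' @param feature_width number of retained components (<= hidden size)
#' @param keep_blank forwarded to \code{\link{tokeniseReport}}
#' @return list with \code{values} (length \code{feature_width}),
#'   \code{score} and \code{record_id}
#' @export
extractReportFeatures <- function(record, encoder, feature_width = 767L,
                                  keep_blank = FALSE) {
  if (feature_width > encoder@hiddenSize)
    stop(sprintf(
      "configuration error: feature_width (%d) exceeds encoder hidden size (%d)",
      feature_width, encoder@hiddenSize))
  tok <- tokeniseReport(record$text, max_len = encoder@maxLen,
                        keep_blank = keep_blank,
                        vocab_size = encoder@vocabSize)
  out <- encodeReport(encoder, tok, attention = FALSE)
  me <- meanEmbedding(out$token_embeddings, out$pad_mask)
  sc <- nodeAttentionScore(out)
  list(values = me[seq_len(feature_width)], score = sc$score,
       record_id = record$record_id)
}

#' Encode a set of reports into an EncodedReports container
#'
#' @param records list of report records (each with \code{record_id},
#'   \code{text})
#' @param encoder a \linkS4class{StubEncoder}
#' @param feature_width retained embedding width (default 767)
#' @param labels optional integer labels in {0, 1}, one per record
#' @param score_method passed to \code{\link{nodeAttentionScore}}
#' @param keep_blank forwarded to the tokeniser
#' @return an \linkS4class{EncodedReports}
#' @export
encodeReports <- function(records, encoder, feature_width = 767L,
                          labels = NULL, score_method = "sum",
                          keep_blank = FALSE) {
  if (feature_width > encoder@hiddenSize)
    stop("configuration error: feature_width exceeds encoder hidden size")
  n <- length(records)
  feats <- matrix(NA_real_, feature_width, n)
  scores <- numeric(n)
  ids <- character(n)
  for (i in seq_len(n)) {
    tok <- tokeniseReport(records[[i]]$text, max_len = encoder@maxLen,
                          keep_blank = keep_blank,
                          vocab_size = encoder@vocabSize)
    out <- encodeReport(encoder, tok, attention = FALSE)
    me <- meanEmbedding(out$token_embeddings, out$pad_mask)
    feats[, i] <- me[seq_len(feature_width)]
    scores[i] <- nodeAttentionScore(out, method = score_method)$score
    ids[i] <- records[[i]]$record_id
  }
  if (anyDuplicated(ids)) stop("record ids must be unique")
  rownames(feats) <- paste0("f", seq_len(feature_width) - 1L)
  colnames(feats) <- ids
  cd <- S4Vectors::DataFrame(record_id = ids, attention_score = scores,
                             row.names = ids)
  if (!is.null(labels)) {
    stopifnot(length(labels) == n, all(labels %in% c(0L, 1L)))
    cd$label <- as.integer(labels)
  }
  new("EncodedReports", SummarizedExperiment::SummarizedExperiment(
    assays = list(features = feats), colData = cd))
}
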