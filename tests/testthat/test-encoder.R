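test_that("tokeniser pads, truncates and is deterministic", {
  tok <- tokeniseReport("ductal carcinoma benign", max_len = 10L)
  expect_length(tok$token_ids, 10L)
  expect_gte(tok$length, 3L)
  expect_true(all(tok$token_ids[(tok$length + 1L):10L] == 0L))
  expect_equal(sum(tok$pad_mask), tok$length)

  long <- paste(rep("stroma", 40L), collapse = " ")
  tok2 <- tokeniseReport(long, max_len = 12L)
  expect_equal(tok2$length, 12L)
  expect_true(all(tok2$pad_mask))

  expect_identical(tokeniseReport("margins clear", max_len = 8L),
                   tokeniseReport("margins clear", max_len = 8L))

  expect_error(tokeniseReport("  ... ", max_len = 8L), "blank report")
  blank <- tokeniseReport(" .. ", max_len = 8L, keep_blank = TRUE)
  expect_equal(blank$length, 2L)  # just [CLS] and [SEP]
  expect_error(tokeniseReport("x", max_len = 1L), "max_len")
})

test_that("stub encoder satisfies the contract: softmax rows, shapes, seed", {
  enc <- stubEncoder(hidden_size = 8L, n_layers = 2L, n_heads = 3L,
                     max_len = 12L, seed = 5L)
  tok <- tokeniseReport("specimen shows benign tissue", max_len = 12L)
  out <- encodeReport(enc, tok)
  expect_equal(dim(out$token_embeddings), c(12L, 8L))
  expect_equal(dim(out$attention_stack), c(2L, 3L, 12L, 12L))
  real <- which(tok$pad_mask)
  sums <- apply(out$attention_stack[, , real, real, drop = FALSE],
                c(1L, 2L, 3L), sum)
  expect_true(all(abs(sums - 1) < 1e-5))
  # pad rows and columns carry zeros
  expect_true(all(out$attention_stack[, , !tok$pad_mask, ] == 0))
  expect_true(all(out$token_embeddings[!tok$pad_mask, ] == 0))

  expect_identical(out, encodeReport(enc, tok))
  enc2 <- stubEncoder(hidden_size = 8L, n_layers = 2L, n_heads = 3L,
                      max_len = 12L, seed = 6L)
  expect_false(identical(encodeReport(enc2, tok)$token_embeddings,
                         out$token_embeddings))
})

test_that("unknown encoder names raise a configuration error naming them", {
  expect_error(makeEncoder("bert-base-uncased"), "bert-base-uncased")
})

test_that("mean embedding: identity, symmetry, and loop oracle", {
  m <- matrix(c(1, 2, 3), 1L, 3L)
  expect_equal(meanEmbedding(m, TRUE), c(1, 2, 3))

  m2 <- rbind(c(0, 2), c(2, 0))
  expect_equal(meanEmbedding(m2, c(TRUE, TRUE)), c(1, 1))

  set.seed(7)
  m3 <- matrix(rnorm(20), 5L, 4L)
  expect_equal(meanEmbedding(m3, rep(TRUE, 5L)), oracle_col_means(m3),
               tolerance = 1e-12)

  expect_error(meanEmbedding(m3, rep(FALSE, 5L)), "empty report")
})

test_that("head averaging: mean of equals, midpoint, loop oracle", {
  a <- array(rep(matrix(1:16 / 16, 4L, 4L), 3L), c(3L, 4L, 4L))
  for (h in 1:3) a[h, , ] <- matrix(1:16 / 16, 4L, 4L)
  expect_equal(headMeanAttention(a), matrix(1:16 / 16, 4L, 4L))

  b <- array(0, c(2L, 3L, 3L))
  b[2L, , ] <- 1
  expect_equal(headMeanAttention(b), matrix(0.5, 3L, 3L))

  set.seed(11)
  cc <- array(runif(3L * 4L * 4L), c(3L, 4L, 4L))
  expect_equal(headMeanAttention(cc), oracle_head_mean(cc),
               tolerance = 1e-12)
})

test_that("node attention score: row-sum identity and masked-sum oracle", {
  # hand-built 1-layer, 1-head, 2-token stack
  stk <- array(0, c(1L, 1L, 2L, 2L))
  stk[1L, 1L, , ] <- rbind(c(0.6, 0.4), c(0.1, 0.9))
  out <- structure(list(attention_stack = stk, pad_mask = c(TRUE, TRUE)),
                   class = "EncoderOutput")
  expect_equal(nodeAttentionScore(out)$score, 2.0)
  expect_equal(nodeAttentionScore(out, method = "mean")$score, 0.5)
  expect_equal(nodeAttentionScore(out, method = "cls_row_sum")$score, 1.0)

  # softmax-normalised rows force score == token count
  enc <- stubEncoder(hidden_size = 6L, n_layers = 2L, n_heads = 2L,
                     max_len = 16L, seed = 3L)
  tok <- tokeniseReport("benign ducts and lobules present", max_len = 16L)
  eo <- encodeReport(enc, tok)
  expect_equal(nodeAttentionScore(eo)$score, tok$length, tolerance = 1e-3)
  expect_equal(nodeAttentionScore(eo)$score,
               oracle_masked_sum(eo$attention_stack, eo$pad_mask),
               tolerance = 1e-8)

  # scores strictly increase with report length
  enc2 <- stubEncoder(hidden_size = 6L, n_layers = 1L, n_heads = 2L,
                      max_len = 256L, seed = 3L)
  lens <- c(10L, 50L, 200L)
  scores <- vapply(lens, function(L) {
    txt <- paste(rep("stroma", L), collapse = " ")
    t1 <- tokeniseReport(txt, max_len = 256L)
    nodeAttentionScore(encodeReport(enc2, t1, attention = FALSE))$score
  }, numeric(1L))
  expect_true(all(diff(scores) > 0))
})

test_that("feature extraction keeps the first feature_width components", {
  enc <- stubEncoder(hidden_size = 16L, n_layers = 1L, n_heads = 2L,
                     max_len = 12L, seed = 2L)
  rec <- make_record("MR1", "invasive carcinoma with clear margins")
  tok <- tokeniseReport(rec$text, max_len = 12L)
  full <- meanEmbedding(encodeReport(enc, tok)$token_embeddings,
                        tok$pad_mask)

  f <- extractReportFeatures(rec, enc, feature_width = 7L)
  expect_length(f$values, 7L)
  expect_equal(f$values, full[1:7], tolerance = 1e-12)

  f16 <- extractReportFeatures(rec, enc, feature_width = 16L)
  expect_equal(f16$values, full, tolerance = 1e-12)

  expect_error(extractReportFeatures(rec, enc, feature_width = 17L),
               "configuration error")
})

test_that("pad positions are inert and module reruns are bit-identical", {
  enc <- stubEncoder(hidden_size = 8L, n_layers = 2L, n_heads = 2L,
                     max_len = 10L, seed = 9L)
  tok <- tokeniseReport("fibrofatty tissue", max_len = 10L)
  out1 <- encodeReport(enc, tok)
  # scrambling pad-position token ids must not change any output
  tok2 <- tok
  tok2$token_ids[!tok2$pad_mask] <- 99L
  out2 <- encodeReport(enc, tok2)
  expect_identical(out1$token_embeddings, out2$token_embeddings)
  expect_identical(out1$attention_stack, out2$attention_stack)

  er1 <- encodeReports(tiny_records(), enc, feature_width = 8L)
  er2 <- encodeReports(tiny_records(), enc, feature_width = 8L)
  expect_identical(SummarizedExperiment::assay(er1),
                   SummarizedExperiment::assay(er2))
  expect_identical(attentionScores(er1), attentionScores(er2))
})

test_that("pooling agrees with brute-force loops on 100 random instances", {
  set.seed(202)
  for (rep in 1:100) {
    n <- sample(2:6, 1L)
    d <- sample(2:5, 1L)
    m <- matrix(rnorm(n * d), n, d)
    mask <- rep(FALSE, n)
    mask[sample(n, sample(n, 1L))] <- TRUE
    expect_equal(meanEmbedding(m, mask),
                 oracle_col_means(m, which(mask)), tolerance = 1e-10)
    a <- array(runif(3L * n * n), c(3L, n, n))
    expect_equal(headMeanAttention(a), oracle_head_mean(a),
                 tolerance = 1e-10)
  }
})
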