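# Synthetic study data: a two-class histopathology-flavoured report corpus
# (class-conditional vocabulary and report lengths) and a directly generated
# encoded dataset that bypasses the text stage. Every generator is a pure
# function of its configuration and seed; no real patient text is shipped.

neutral_terms <- c(
  "specimen", "received", "formalin", "sections", "examined", "microscopy",
  "shows", "fibrofatty", "tissue", "ducts", "lobules", "stroma", "benign",
  "epithelium", "margins", "clear", "biopsy", "core", "breast", "left",
  "right", "upper", "outer", "quadrant", "grade", "tubule", "formation",
  "nuclear", "pleomorphism", "mitotic", "count", "impression", "clinical",
  "details", "gross", "findings", "lesion", "measuring", "firm", "mass")

marker_phrases <- c(
  "metastatic deposit identified", "lymphovascular invasion present",
  "axillary lymph node involvement", "extranodal extension seen",
  "tumour emboli within vessels", "distant spread suspected",
  "perineural invasion noted", "multiple nodes positive")

#' Synthetic data configuration
#'
#' Defaults emulate the study conditions the pipeline assumes: 1000 records,
#' two balanced classes, 767 embedding columns of which 5 carry a 3-sigma
#' class mean shift, and class-conditional attention-score (report-length)
#' distributions that overlap only partially.
#'
#' @param n number of records (default 1000)
#' @param class_balance probability of class 1 (default 0.5)
#' @param p embedding width for the encoded generator (default 767)
#' @param informative_dims columns carrying class signal; NULL (default)
#'   places 5 dimensions evenly across the width
#' @param effect_size class mean shift, in noise-sd units (default 3)
#' @param noise_sd feature noise scale (default 1)
#' @param len0,len1 report token-length distributions per class:
#'   c(mean, sd); defaults N(120, 40) and N(280, 60), clipped to
#'   [10, 600] — lengths straddle typical max_len settings so padding and
#'   truncation paths are both exercised
#' @param marker_rate1,marker_rate0 per-sentence marker-phrase rates
#' @param score0,score1 class-conditional attention-score distributions for
#'   the encoded generator, c(mean, sd) (mirrors the token-count scale)
#' @param seed generator seed
#' @export
syntheticConfig <- function(n = 1000L, class_balance = 0.5, p = 767L,
                            informative_dims = NULL,
                            effect_size = 3, noise_sd = 1,
                            len0 = c(120, 40), len1 = c(280, 60),
                            marker_rate1 = 0.08, marker_rate0 = 0.005,
                            score0 = c(120, 40), score1 = c(280, 60),
                            seed = 1L) {
  if (is.null(informative_dims))
    informative_dims <- unique(pmax(1L, round(seq(0.02, 0.8,
                                                  length.out = 5L) * p)))
  stopifnot(n >= 2L, class_balance >= 0, class_balance <= 1,
            effect_size >= 0, all(informative_dims >= 1L),
            all(informative_dims <= p))
  structure(list(n = as.integer(n), class_balance = class_balance,
                 p = as.integer(p),
                 informative_dims = as.integer(informative_dims),
                 effect_size = effect_size, noise_sd = noise_sd,
                 len0 = len0, len1 = len1,
                 marker_rate1 = marker_rate1, marker_rate0 = marker_rate0,
                 score0 = score0, score1 = score1, seed = as.integer(seed)),
            class = "SyntheticConfig")
}

draw_labels <- function(cfg) {
  n1 <- round(cfg$n * cfg$class_balance)
  sample(rep(c(1L, 0L), c(n1, cfg$n - n1)))
}

#' Generate a synthetic report corpus
#'
#' Class-1 reports contain metastasis-flavoured marker phrases at an
#' elevated rate and are drawn longer on average, so both the embedding and
#' the attention-score (token count) channels carry class signal.
#'
#' @param cfg a \code{\link{syntheticConfig}}
#' @return list with \code{records} (each a list with \code{record_id},
#'   \code{text}) and \code{labels}
#' @export
generateReports <- function(cfg = syntheticConfig()) {
  with_local_seed(cfg$seed, {
    labels <- draw_labels(cfg)
    records <- vector("list", cfg$n)
    for (i in seq_len(cfg$n)) {
      lp <- if (labels[i] == 1L) cfg$len1 else cfg$len0
      len <- max(10L, min(600L, round(rnorm(1L, lp[1L], lp[2L]))))
      rate <- if (labels[i] == 1L) cfg$marker_rate1 else cfg$marker_rate0
      words <- sample(neutral_terms, len, replace = TRUE)
      n_marker <- rbinom(1L, max(1L, len %/% 10L), rate * 10)
      if (n_marker > 0L) {
        phr <- sample(marker_phrases, n_marker, replace = TRUE)
        pos <- sample(len, n_marker)
        words[pos] <- phr
      }
      records[[i]] <- list(record_id = sprintf("MR%05d", i),
                           text = paste(words, collapse = " "))
    }
    list(records = records, labels = labels)
  })
}

#' Generate an encoded dataset directly
#'
#' Bypasses the text stage: Gaussian features with class-shifted means on
#' the informative dimensions only, and attention scores drawn from
#' class-conditional normal distributions (clipped at 1), mirroring the
#' token-count scale of the sum score.
#'
#' @param cfg a \code{\link{syntheticConfig}}
#' @return an \linkS4class{EncodedReports} with labels in colData
#' @export
generateEncodedDataset <- function(cfg = syntheticConfig()) {
  with_local_seed(cfg$seed, {
    labels <- draw_labels(cfg)
    X <- matrix(rnorm(cfg$n * cfg$p, sd = cfg$noise_sd), cfg$n, cfg$p)
    shift <- cfg$effect_size * cfg$noise_sd
    X[labels == 1L, cfg$informative_dims] <-
      X[labels == 1L, cfg$informative_dims] + shift
    sp <- rbind(cfg$score0, cfg$score1)[labels + 1L, , drop = FALSE]
    scores <- pmax(1, rnorm(cfg$n, sp[, 1L], sp[, 2L]))
    ids <- sprintf("MR%05d", seq_len(cfg$n))
    feats <- t(X)
    rownames(feats) <- paste0("f", seq_len(cfg$p) - 1L)
    colnames(feats) <- ids
    cd <- S4Vectors::DataFrame(record_id = ids, attention_score = scores,
                               label = labels, row.names = ids)
    new("EncodedReports", SummarizedExperiment::SummarizedExperiment(
      assays = list(features = feats), colData = cd))
  })
}

#' Records x features matrix of an EncodedReports
#'
#' @param x an \linkS4class{EncodedReports}
#' @return numeric matrix, one row per report
#' @export
featureMatrix <- function(x) {
  stopifnot(is(x, "EncodedReports"))
  t(SummarizedExperiment::assay(x, "features"))
}
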