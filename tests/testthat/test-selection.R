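test_that("normalisation: zero mean, unit variance, constant columns zero", {
  x <- cbind(a = c(2, 4, 6), b = c(5, 5, 5))
  xs <- normaliseFeatures(x)
  expect_equal(mean(xs[, "a"]), 0, tolerance = 1e-12)
  expect_equal(var(xs[, "a"]), 1, tolerance = 1e-12)
  expect_equal(unname(xs[, "b"]), c(0, 0, 0))

  set.seed(8)
  y <- matrix(rnorm(100, mean = 3, sd = 7), 20L, 5L)
  ys <- normaliseFeatures(y)
  expect_true(all(abs(oracle_col_means(ys)) < 1e-10))
  for (j in 1:5) expect_equal(var(ys[, j]), 1, tolerance = 1e-10)
})

test_that("univariate F: conventions and the textbook two-group formula", {
  set.seed(1)
  n <- 200L
  y <- rep(c(0L, 1L), each = n / 2L)
  X <- cbind(g = c(rnorm(n / 2L, 0), rnorm(n / 2L, 2)),  # delta mu = 2 sigma
             const = rep(5, n),
             sep = as.numeric(y),
             noise = rnorm(n))
  r <- univariateScores(X, y)
  expect_equal(unname(r$score["const"]), 0)
  expect_equal(unname(r$rank["sep"]), 1L)  # perfect separation ranks first

  # independent textbook F for the Gaussian column
  g0 <- X[y == 0L, "g"]; g1 <- X[y == 1L, "g"]
  ssb <- length(g0) * (mean(g0) - mean(X[, "g"]))^2 +
    length(g1) * (mean(g1) - mean(X[, "g"]))^2
  ssw <- sum((g0 - mean(g0))^2) + sum((g1 - mean(g1))^2)
  f_direct <- ssb / (ssw / (n - 2L))
  expect_equal(unname(r$score["g"]), f_direct, tolerance = 1e-10)
  # and against R's own one-way ANOVA
  f_aov <- summary(aov(X[, "g"] ~ factor(y)))[[1]][["F value"]][1L]
  expect_equal(unname(r$score["g"]), f_aov, tolerance = 1e-8)

  expect_error(univariateScores(X, rep(1L, n)), "both classes")
})

test_that("extra-trees importance: normalised, seeded, finds the signal", {
  set.seed(3)
  n <- 500L
  y <- rep(c(0L, 1L), each = n / 2L)
  X <- matrix(rnorm(n * 50L), n, 50L)
  X[y == 1L, 7L] <- X[y == 1L, 7L] + 2
  colnames(X) <- paste0("f", 0:49)
  r <- extraTreesImportance(X, y, n_trees = 50L, seed = 3L)
  expect_equal(sum(r$score), 1, tolerance = 1e-6)
  expect_true(all(r$score >= 0))
  expect_equal(unname(r$rank["f6"]), 1L)

  r2 <- extraTreesImportance(X, y, n_trees = 50L, seed = 3L)
  expect_identical(r$rank, r2$rank)

  # the informative column ranks first across independently seeded runs
  hits <- vapply(1:20, function(s) {
    set.seed(1000L + s)
    Xi <- matrix(rnorm(300L * 30L), 300L, 30L)
    yi <- rep(c(0L, 1L), each = 150L)
    Xi[yi == 1L, 4L] <- Xi[yi == 1L, 4L] + 2
    colnames(Xi) <- paste0("f", 0:29)
    unname(extraTreesImportance(Xi, yi, n_trees = 50L,
                                seed = s)$rank["f3"]) == 1L
  }, logical(1L))
  expect_gte(mean(hits), 0.95)
})

test_that("SHAP: local accuracy, null features, Shapley oracle equivalence", {
  set.seed(12)
  n <- 120L
  X <- cbind(f0 = rnorm(n), f1 = rnorm(n), f2 = rnorm(n))
  y <- as.integer(X[, 1L] + 0.5 * X[, 2L] > 0)
  tr <- extraTreesImportance(X, y, n_trees = 25L, seed = 4L, max_depth = 4L)
  sh <- shapImportance(tr, X)

  # local accuracy against ranger's own predictions
  pred <- predict(tr$model, as.data.frame(X))$predictions[, "1"]
  expect_lt(max(abs(rowSums(sh$phi) + sh$base - pred)), 1e-4)

  # exhaustive coalition-enumeration oracle on a small forest
  fo <- TextGraphNet:::flatten_forest(tr$model, X)
  for (r in c(1L, 17L, 60L))
    expect_equal(sh$phi[r, ], oracle_tree_shapley(fo, X[r, ], 3L),
                 tolerance = 1e-10)

  # a column the trees never split on gets exactly zero attribution
  Xn <- cbind(X, dead = rep(1, n))  # constant: never a valid split
  trn <- extraTreesImportance(Xn, y, n_trees = 25L, seed = 4L, max_depth = 4L)
  shn <- shapImportance(trn, Xn)
  expect_equal(unname(shn$score["dead"]), 0)

  # model/feature mismatch is an error
  expect_error(shapImportance(tr, Xn), "mismatch")
})

test_that("depth-1 single tree matches two-player Shapley by hand", {
  # stump on f0 at 0: leaf values 0.2 (left) and 0.8 (right); covers 6/4
  forest <- list(left = c(1L, -1L, -1L), right = c(2L, -1L, -1L),
                 feature = c(0L, 0L, 0L), threshold = c(0, 0, 0),
                 value = c(0, 0.2, 0.8), cover = c(10, 6, 4),
                 tree_start = c(0L, 3L))
  x <- c(-1, 5)  # goes left
  res <- TextGraphNet:::.treeshap_cpp(matrix(x, 1L), forest$left,
                                      forest$right, forest$feature,
                                      forest$threshold, forest$value,
                                      forest$cover, forest$tree_start)
  base <- 0.6 * 0.2 + 0.4 * 0.8  # cover-weighted leaf mean = 0.44
  # f0 carries the full difference to the reached leaf; f1 is a null player
  expect_equal(res$base, base)
  expect_equal(res$phi[1L, ], c(0.2 - base, 0))
  expect_equal(res$phi[1L, ], oracle_tree_shapley(forest, x, 2L),
               tolerance = 1e-12)
})

test_that("mean-rank aggregation and top-k selection", {
  mk <- function(name, ranks, ids = c("a", "b", "c")) {
    r <- list(selector = name, score = setNames(-ranks, ids),
              rank = setNames(as.integer(ranks), ids), column_ids = ids)
    class(r) <- "SelectorRanking"
    r
  }
  # hand-computed mean ranks: a 2.0, b 5/3, c 7/3 -> [b, a]
  sel <- aggregateAndSelect(list(mk("u", c(1, 2, 3)), mk("t", c(2, 1, 3)),
                                 mk("s", c(3, 2, 1))), k = 2L)
  expect_equal(sel$selected, c("b", "a"))
  expect_equal(unname(sel$mean_rank), c(2, 5 / 3, 7 / 3))

  # three identical rankings -> that ranking's first k columns
  same <- aggregateAndSelect(list(mk("u", c(2, 3, 1)), mk("t", c(2, 3, 1)),
                                  mk("s", c(2, 3, 1))), k = 2L)
  expect_equal(same$selected, c("c", "a"))

  # k = p returns all columns ordered by mean rank
  all3 <- aggregateAndSelect(list(mk("u", c(1, 2, 3)), mk("t", c(2, 1, 3)),
                                  mk("s", c(3, 2, 1))), k = 3L)
  expect_equal(all3$selected, c("b", "a", "c"))

  expect_error(aggregateAndSelect(
    list(mk("u", c(1, 2, 3)), mk("t", c(1, 2), ids = c("a", "b"))), k = 1L),
    "inconsistent")
})

test_that("selection output size is exactly k and order-invariant", {
  set.seed(21)
  n <- 120L; p <- 25L
  X <- matrix(rnorm(n * p), n, p)
  y <- rep(c(0L, 1L), each = n / 2L)
  X[y == 1L, c(2L, 9L)] <- X[y == 1L, c(2L, 9L)] + 1.5
  colnames(X) <- paste0("f", seq_len(p) - 1L)
  for (k in c(1L, 5L, p)) {
    sel <- selectFeatures(X, y, k = k, n_trees = 30L, seed = 5L)
    expect_length(sel$selected, k)
  }
  sel5 <- selectFeatures(X, y, k = 5L, n_trees = 30L, seed = 5L)
  expect_true(all(c("f1", "f8") %in% sel5$selected))
})
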