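test_that("confusion matrix counts match a double-loop oracle", {
  expect_equal(unname(confusion_matrix(c(0, 0, 1), c(0, 1, 1), 2)),
               matrix(c(1L, 0L, 1L, 1L), 2))
  y <- rep(0:4, each = 3)
  cmp <- confusion_matrix(y, y)
  expect_equal(unname(cmp), diag(3L, 5))
  set.seed(71)
  y_true <- sample(0:4, 200, replace = TRUE)
  y_pred <- sample(0:4, 200, replace = TRUE)
  cm <- confusion_matrix(y_true, y_pred)
  oracle <- matrix(0L, 5, 5)
  for (i in 0:4) for (j in 0:4)
    oracle[i + 1, j + 1] <- sum(y_true == i & y_pred == j)
  expect_equal(unname(cm), oracle)
  expect_equal(rowSums(cm), class_counts(y_true), ignore_attr = TRUE)
  expect_error(confusion_matrix(c(0, 5), c(0, 0)), "out of range")
})

test_that("precision/recall handle perfect and degenerate cases", {
  d <- diag(3L, 5)
  pr <- precision_recall(d)
  expect_equal(pr$precision, rep(1, 5))
  expect_equal(pr$recall, rep(1, 5))
  # class never predicted: precision 0, flagged
  cm <- confusion_matrix(c(0, 0, 1, 1), c(1, 1, 1, 1), 2)
  pr2 <- precision_recall(cm)
  expect_equal(pr2$precision[1], 0)
  expect_true(pr2$flagged[1])
})

test_that("MAP/WAP/WR agree with a brute-force tally on random pairs", {
  set.seed(73)
  for (rep in 1:25) {
    n <- sample(20:200, 1)
    y_true <- sample(0:4, n, replace = TRUE)
    y_pred <- sample(0:4, n, replace = TRUE)
    cm <- confusion_matrix(y_true, y_pred)
    sm <- summary_metrics(cm)
    oracle <- tally_metrics(y_true, y_pred)
    expect_equal(sm$MAP, oracle$MAP)
    expect_equal(sm$WAP, oracle$WAP)
    expect_equal(sm$WR, oracle$WR)
    # WR is identically the micro accuracy
    expect_equal(sm$WR, sum(diag(cm)) / sum(cm))
  }
})

test_that("MAP arithmetic and the balanced-set WAP=MAP identity hold", {
  # a confusion matrix with prescribed per-class precisions
  # columns sums 4, diagonals 4, 2, 3, 1, 2 -> precisions 1, .5, .75, .25, .5
  cm <- matrix(0L, 5, 5)
  diag(cm) <- c(4L, 2L, 3L, 1L, 2L)
  off <- c(4, 2, 3, 1, 2)
  for (j in 1:5) {
    need <- 4L - cm[j, j]
    if (need > 0) cm[(j %% 5) + 1, j] <- cm[(j %% 5) + 1, j] + need
  }
  expect_equal(colSums(cm), rep(4, 5), ignore_attr = TRUE)
  expect_equal(summary_metrics(cm)$MAP, mean(c(1, .5, .75, .25, .5)))
  # balanced true classes make the weights uniform, so WAP = MAP
  set.seed(74)
  y_true <- rep(0:4, each = 30)
  y_pred <- sample(0:4, 150, replace = TRUE)
  sm <- summary_metrics(confusion_matrix(y_true, y_pred))
  expect_equal(sm$alpha, rep(0.2, 5))
  expect_equal(sm$WAP, sm$MAP)
})

test_that("balanced test sets downsample every class to the minimum", {
  L <- simulate_labeled_set(generator_spec(
    class_counts = c(16, 75, 87, 128, 44), seed = 75))
  bal <- balance_test_set(L, seed = 1)
  expect_equal(class_counts(bal), rep(16L, 5))
  expect_equal(imbalance_ratio(bal), 1)
  # subset without replacement: every balanced row exists in the source
  key <- function(m) apply(unclass(m), 1, function(r) paste(r, collapse = ","))
  expect_true(all(key(bal$spectra) %in% key(L$spectra)))
  expect_identical(class_counts(balance_test_set(L, seed = 1)),
                   class_counts(bal))
  # already balanced: counts unchanged
  Lb <- simulate_labeled_set(generator_spec(class_counts = rep(9L, 5),
                                            seed = 76))
  expect_equal(class_counts(balance_test_set(Lb, seed = 2)), rep(9L, 5))
  L0 <- simulate_labeled_set(generator_spec(class_counts = c(0, 5, 5, 5, 5),
                                            seed = 77))
  expect_error(balance_test_set(L0), "empty")
})

test_that("cross-validation returns per-fold WAP and their mean", {
  L <- simulate_labeled_set(generator_spec(class_counts = rep(12L, 5),
                                           effect_size = 4, seed = 78))
  U <- toy_matrix(30, seed = 79)
  cv <- cross_validate(L, U, folds = 3, seed = 2, base = "lda", tau = 2,
                       max_iter = 0, beta = 2)
  expect_length(cv$wap, 3)
  expect_equal(cv$mean_wap, mean(cv$wap))
  # noiseless separable data: a fold-trained model scores perfectly
  spec0 <- generator_spec(class_counts = rep(10L, 5), effect_size = 40,
                          noise_sd = 0.001, scatter_sd = 0, seed = 80)
  L0 <- simulate_labeled_set(spec0)
  cv0 <- cross_validate(L0, U, folds = 2, seed = 3, base = "lda", tau = 2,
                        max_iter = 0, beta = 1)
  expect_equal(cv0$mean_wap, 1)
})

test_that("node Gini values follow the pairwise-product definition", {
  expect_equal(nirssl:::gini_index(c(1, 0, 0)), 0)       # pure node
  expect_equal(nirssl:::gini_index(c(0.5, 0.5)), 0.5)    # 50/50 node
  p <- c(0.2, 0.3, 0.1, 0.25, 0.15)
  expect_equal(nirssl:::gini_index(p), 1 - sum(p^2))
})

test_that("Gini importance recovers a planted informative band", {
  set.seed(81)
  hits <- vapply(1:8, function(s) {
    n <- 80
    X <- matrix(runif(n * 20), n)
    y <- as.integer(X[, 7] > 0.5)   # band 7 fully decides the class
    m <- fit_base("rfc", spectrum_matrix(X, 1:20), y, seed = s, ntree = 60)
    imp <- gini_importance(m)
    imp$top_bands[1] == 7
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("weighted Gini importance is non-negative and normalized; the
           literal mode differs", {
  L <- simulate_labeled_set(generator_spec(class_counts = rep(15L, 5),
                                           effect_size = 3, seed = 82))
  m <- fit_base("rfc", L$spectra, L$labels, seed = 4, ntree = 40)
  w <- gini_importance(m, mode = "weighted")
  expect_true(all(w$gini >= -1e-12))
  expect_equal(sum(w$gini), 1)
  lit <- gini_importance(m, mode = "literal")
  expect_false(identical(w$gini, lit$gini))
  # an auxiliary forest serves non-tree models
  ml <- fit_base("lda", L$spectra, L$labels)
  aux <- gini_importance(ml, ntree = 40, seed = 5)
  expect_equal(sum(aux$gini), 1)
  mnd <- fit_base("lda", L$spectra, L$labels, keep_data = FALSE)
  expect_error(gini_importance(mnd), "keep_data")
})

test_that("band-concentration Pearson correlation behaves linearly", {
  set.seed(83)
  conc <- runif(30, 2.5, 4)
  X <- matrix(rnorm(30 * 4), 30)
  X[, 2] <- 2 * conc + 3
  X[, 3] <- -conc
  X[, 4] <- 1           # constant band
  r <- band_element_correlation(spectrum_matrix(X + 10, 1:4), conc)
  expect_equal(r[2], 1)
  expect_equal(r[3], -1)
  expect_equal(r[4], 0)
  expect_equal(attr(r, "flagged"), 4L)
  # null band: |r| small with high probability at n = 1000
  set.seed(84)
  Xn <- matrix(rnorm(1000), 1000, 1)
  rn <- band_element_correlation(spectrum_matrix(Xn, 1), runif(1000))
  expect_lt(abs(rn[1]), 0.1)
  expect_error(band_element_correlation(spectrum_matrix(X, 1:4), rep(3, 30)),
               "constant")
})
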