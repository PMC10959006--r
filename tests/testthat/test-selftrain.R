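test_that("the beta quota controls how much unlabeled data is injected", {
  pool <- toy_matrix(500, seed = 51)
  expect_equal(nrow(subsample_unlabeled(pool, 1 / 4, 100, seed = 1)), 400)
  expect_equal(nrow(subsample_unlabeled(pool, 1 / 2, 100, seed = 1)), 200)
  # beta = 1 with quota equal to the pool: the whole pool, no warning
  expect_silent(w <- subsample_unlabeled(pool, 1, 500, seed = 1))
  expect_identical(unclass(w), unclass(pool))
  # pool smaller than quota: clamp with warning
  expect_warning(u <- subsample_unlabeled(pool, 1 / 8, 100, seed = 1),
                 "smaller than quota")
  expect_equal(nrow(u), 500)
  expect_error(subsample_unlabeled(pool, 0, 10), "positive")
  # deterministic
  expect_identical(unclass(subsample_unlabeled(pool, 1 / 4, 100, seed = 5)),
                   unclass(subsample_unlabeled(pool, 1 / 4, 100, seed = 5)))
})

test_that("pseudo-labeling equals a brute-force confidence filter", {
  L <- simulate_labeled_set(generator_spec(class_counts = rep(15L, 5),
                                           effect_size = 3, seed = 53))
  U <- simulate_labeled_set(generator_spec(class_counts = rep(20L, 5),
                                           effect_size = 3, seed = 54))$spectra
  m <- fit_base("rfc", L$spectra, L$labels, seed = 1, ntree = 100)
  prob <- predict(m, U, type = "prob")
  for (tau in c(0.3, 0.6, 0.9)) {
    pl <- pseudo_label(m, U, tau)
    oracle_idx <- which(apply(prob, 1, max) >= tau)
    expect_identical(pl$idx, oracle_idx)
    expect_identical(pl$labels,
                     as.integer(max.col(prob, "first") - 1L)[oracle_idx])
    expect_true(all(pl$conf >= tau))
  }
  # boundaries
  expect_length(pseudo_label(m, U, 1.01)$idx, 0)
  expect_length(pseudo_label(m, U, 1e-9)$idx, nrow(U))
})

test_that("tau > 1 and max_iter = 0 reproduce the supervised fit exactly", {
  L <- simulate_labeled_set(generator_spec(class_counts = c(5, 8, 12, 15, 10),
                                           seed = 57))
  U <- simulate_labeled_set(generator_spec(class_counts = rep(25L, 5),
                                           seed = 58))$spectra
  Te <- toy_matrix(40, seed = 59)
  for (b in c("rfc", "plsda")) {
    sup <- fit_base(b, L$spectra, L$labels, seed = 1 + 303L, ntree = 50)
    m0 <- self_train(L$spectra, L$labels, unlabeled = U, base = b, beta = 1,
                     max_iter = 0, seed = 1, ntree = 50)
    expect_identical(predict(m0, Te, type = "prob"),
                     predict(sup, Te, type = "prob"), label = b)
    m1 <- suppressWarnings(
      self_train(L$spectra, L$labels, unlabeled = U, base = b, beta = 1,
                 tau = 1.5, max_iter = 5, seed = 1, ntree = 50))
    expect_identical(predict(m1, Te, type = "prob"),
                     predict(sup, Te, type = "prob"), label = b)
  }
})

test_that("MES and SMOTE pseudo-samplers keep mu at exactly 1", {
  L <- simulate_labeled_set(generator_spec(
    class_counts = c(6, 26, 37, 58, 23), effect_size = 3, seed = 61))
  U <- simulate_labeled_set(generator_spec(class_counts = rep(60L, 5),
                                           effect_size = 3, seed = 62))$spectra
  for (ps in c("mes", "smote")) {
    fit <- self_train(L$spectra, L$labels, unlabeled = U, base = "lda",
                      beta = 1 / 2, tau = 0.5, max_iter = 5,
                      pseudo_sampler = ps, stop_eps = 0, seed = 3)
    expect_gt(nrow(fit$history), 0)
    expect_true(all(fit$history$mu == 1), label = ps)
    cnts <- as.matrix(fit$history[, paste0("count_", 0:4)])
    live <- cnts[, colSums(cnts) > 0, drop = FALSE]
    expect_true(all(apply(live, 1, function(r) length(unique(r[r > 0])) == 1)),
                label = paste(ps, "equal per-class counts"))
  }
})

test_that("the full run is deterministic given the seed", {
  L <- simulate_labeled_set(generator_spec(class_counts = c(5, 10, 15, 20, 10),
                                           effect_size = 2, seed = 63))
  U <- simulate_labeled_set(generator_spec(class_counts = rep(30L, 5),
                                           effect_size = 2, seed = 64))$spectra
  f1 <- self_train(L$spectra, L$labels, unlabeled = U, base = "rfc",
                   tau = 0.6, max_iter = 3, seed = 11, ntree = 50)
  f2 <- self_train(L$spectra, L$labels, unlabeled = U, base = "rfc",
                   tau = 0.6, max_iter = 3, seed = 11, ntree = 50)
  expect_identical(f1$history, f2$history)
  expect_identical(predict(f1, L$spectra, type = "prob"),
                   predict(f2, L$spectra, type = "prob"))
})

test_that("history bookkeeping and convergence flags are consistent", {
  L <- simulate_labeled_set(generator_spec(class_counts = rep(15L, 5),
                                           effect_size = 4, seed = 65))
  U <- simulate_labeled_set(generator_spec(class_counts = rep(40L, 5),
                                           effect_size = 4, seed = 66))$spectra
  fit <- self_train(L$spectra, L$labels, unlabeled = U, base = "lda",
                    tau = 0.5, max_iter = 10, stop_eps = 0.05, seed = 2)
  expect_lte(nrow(fit$history), 10)
  if (fit$converged) {
    last <- fit$history$changed_frac[nrow(fit$history)]
    expect_lt(last, 0.05)
  }
  # pseudo counts never exceed the high-confidence supply
  expect_true(all(fit$history$n_pseudo <= fit$history$n_high_confidence))
})

test_that("SMOTE labeled sampling paired with RES warns", {
  L <- simulate_labeled_set(generator_spec(class_counts = c(5, 8, 10, 12, 15),
                                           seed = 67))
  U <- toy_matrix(100, seed = 68)
  expect_warning(self_train(L$spectra, L$labels, unlabeled = U, base = "lda",
                            max_iter = 1, labeled_sampler = "smote",
                            pseudo_sampler = "res", seed = 1),
                 "raw skewed")
})
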