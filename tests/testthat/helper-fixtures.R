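# small in-code fixtures shared across test files

toy_matrix <- function(n = 5, wl = default_wavelength_grid(), seed = 1) {
  set.seed(seed)
  spectrum_matrix(matrix(runif(n * length(wl), 0.2, 0.8), n), wl)
}

# tiny labeled CSV on disk; returns the path
write_fixture_csv <- function(labels = 0:4, conc = NULL, n_bands = 224) {
  wl <- default_wavelength_grid()[seq_len(n_bands)]
  n <- max(length(labels), length(conc))
  df <- as.data.frame(matrix(runif(n * n_bands, 0.2, 0.8), n))
  names(df) <- sprintf("band_%06.1f", wl)
  if (!is.null(labels)) df$label <- labels
  if (!is.null(conc)) df$concentration_pct <- conc
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  path
}

small_cube_spec <- function(seed = 5, ...) {
  generator_spec(class_counts = c(1, 1, 1, 1, 1), seed = seed, ...)
}

# windows an nm value must fall into for planted-signal recovery checks
in_default_windows <- function(nm) {
  (nm >= 945 & nm <= 980) | (nm >= 1548 & nm <= 1592) |
    (nm >= 1651 & nm <= 1680)
}

# brute-force tally of TP/FP/FN per class, independent of confusion_matrix
tally_metrics <- function(y_true, y_pred, k1 = 5) {
  prec <- rec <- numeric(k1)
  for (cls in 0:(k1 - 1)) {
    tp <- sum(y_true == cls & y_pred == cls)
    fp <- sum(y_true != cls & y_pred == cls)
    fn <- sum(y_true == cls & y_pred != cls)
    prec[cls + 1] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[cls + 1] <- if (tp + fn > 0) tp / (tp + fn) else 0
  }
  alpha <- vapply(0:(k1 - 1), function(cls) mean(y_true == cls), numeric(1))
  list(precision = prec, recall = rec,
       MAP = sum(prec) / k1, WAP = sum(alpha * prec),
       WR = sum(alpha * rec))
}

# independent NIPALS PLS2 oracle (classic deflation algorithm)
nipals_pls2 <- function(X, Y, ncomp, tol = 1e-10) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  xm <- colMeans(X); ym <- colMeans(Y)
  E <- sweep(X, 2, xm); F_ <- sweep(Y, 2, ym)
  W <- P <- NULL; Q <- NULL; Tm <- NULL
  for (a in seq_len(ncomp)) {
    u <- F_[, which.max(apply(F_, 2, var))]
    repeat {
      w <- crossprod(E, u); w <- w / sqrt(sum(w^2))
      t_ <- E %*% w
      q <- crossprod(F_, t_) / sum(t_^2)
      u_new <- F_ %*% q / sum(q^2)
      if (sum((u_new - u)^2) < tol * sum(u_new^2)) { u <- u_new; break }
      u <- u_new
    }
    t_ <- E %*% w
    p <- crossprod(E, t_) / sum(t_^2)
    q <- crossprod(F_, t_) / sum(t_^2)
    E <- E - t_ %*% t(p)
    F_ <- F_ - t_ %*% t(q)
    W <- cbind(W, w); P <- cbind(P, p); Q <- cbind(Q, q)
  }
  B <- W %*% solve(crossprod(P, W)) %*% t(Q)
  list(predict = function(Xn)
    sweep(as.matrix(Xn), 2, xm) %*% B +
      matrix(ym, nrow(Xn), length(ym), byrow = TRUE))
}
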