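# ---- PLS2 core ---------------------------------------------------------
# Modified kernel algorithm (covariance-based): works on X'Y and X'X only,
# so cost is driven by the band count, not the sample count. Used by PLS-DA
# with one-hot class targets.
pls2_fit <- function(X, Y, ncomp) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- sweep(X, 2, xm); Yc <- sweep(Y, 2, ym)
  p <- ncol(X); m <- ncol(Y)
  ncomp <- min(ncomp, p, nrow(X) - 1L)
  A <- crossprod(Xc, Yc)          # p x m covariance block
  M <- crossprod(Xc)              # p x p
  R <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); Q <- matrix(0, m, ncomp)
  used <- 0L
  for (a in seq_len(ncomp)) {
    w <- if (m == 1L) A else A %*% eigen(crossprod(A),
                                         symmetric = TRUE)$vectors[, 1]
    nw <- sqrt(sum(w^2))
    if (nw <= 1e-12) break
    w <- w / nw
    r <- w
    if (a > 1L) for (j in seq_len(a - 1L))
      r <- r - as.numeric(crossprod(P[, j], w)) * R[, j]
    tt <- as.numeric(crossprod(r, M %*% r))
    if (tt <= .Machine$double.eps) break
    pv <- (M %*% r) / tt
    qv <- crossprod(A, r) / tt
    A <- A - tt * pv %*% t(qv)
    R[, a] <- r; P[, a] <- pv; Q[, a] <- qv
    used <- a
  }
  if (used == 0L) stop("PLS found no usable component (constant predictors?)")
  ncomp <- used
  B <- R[, seq_len(ncomp), drop = FALSE] %*% t(Q[, seq_len(ncomp), drop = FALSE])
  list(coef = B, x_mean = xm, y_mean = ym, ncomp = ncomp)
}

pls2_predict <- function(fit, Xnew) {
  sweep(as.matrix(Xnew), 2, fit$x_mean) %*% fit$coef +
    matrix(fit$y_mean, nrow(Xnew), length(fit$y_mean), byrow = TRUE)
}

softmax_rows <- function(s) {
  s <- s - apply(s, 1, max)
  e <- exp(s)
  e / rowSums(e)
}

#' Fit a base spectral classifier
#'
#' The three base classifiers used inside self-training: partial least
#' squares discriminant analysis ("plsda": PLS2 regression on one-hot class
#' targets with an argmax decision, implemented in-package), linear
#' discriminant analysis ("lda", via \pkg{MASS}) and a random forest
#' ("rfc", via \pkg{randomForest}). All three expose hard class predictions
#' and per-class probability scores summing to 1 through
#' [predict.base_classifier()].
#'
#' @param base "plsda", "lda" or "rfc".
#' @param x A [spectrum_matrix()] (or plain matrix) of training spectra.
#' @param y Integer class labels 0--4.
#' @param seed Integer seed (controls the forest; the linear fits are
#'   deterministic).
#' @param ncomp Number of PLS latent variables (PLS-DA only).
#' @param ntree Number of trees (random forest only).
#' @param keep_data Store the training data in the model (needed for the
#'   auxiliary forest of [gini_importance()]).
#' @return A `base_classifier` object.
#' @export
fit_base <- function(base = c("plsda", "lda", "rfc"), x, y, seed = 1L,
                     ncomp = 10L, ntree = 200L, keep_data = TRUE) {
  base <- match.arg(tolower(base), c("plsda", "lda", "rfc"))
  m <- unclass(x)
  y <- as.integer(y)
  stopifnot(nrow(m) == length(y))
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("training data contains a single class")
  fit <- switch(base,
    plsda = {
      Y <- outer(y, classes, `==`) * 1
      pls2_fit(m, Y, ncomp)
    },
    lda = {
      # drop zero-variance bands (e.g. all-equal columns) that break the
      # within-class scaling
      keep <- apply(m, 2, function(col) stats::sd(col) > 1e-12)
      list(lda = suppressWarnings(MASS::lda(m[, keep, drop = FALSE],
                                            grouping = factor(y))),
           keep = keep)
    },
    rfc = {
      set.seed(seed)
      randomForest::randomForest(m, factor(y, levels = classes),
                                 ntree = ntree)
    })
  structure(list(base = base, fit = fit, classes = classes,
                 seed = as.integer(seed),
                 train_x = if (keep_data) m, train_y = if (keep_data) y),
            class = "base_classifier")
}

#' Predict from a base classifier
#'
#' @param object A [fit_base()] model.
#' @param newdata Spectra on the same band grid.
#' @param type "class" for hard 0--4 labels (ties broken toward the lowest
#'   class index), "prob" for a matrix of per-class scores summing to 1.
#'   Columns of the probability matrix are named by class index; classes
#'   absent from training get probability 0.
#' @param ... Unused.
#' @export
predict.base_classifier <- function(object, newdata,
                                    type = c("class", "prob"), ...) {
  type <- match.arg(type)
  m <- unclass(newdata)
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  prob_sub <- switch(object$base,
    plsda = softmax_rows(pls2_predict(object$fit, m)),
    lda = {
      pr <- stats::predict(object$fit$lda,
                           m[, object$fit$keep, drop = FALSE])
      pr$posterior
    },
    rfc = stats::predict(object$fit, m, type = "prob"))
  prob <- matrix(0, nrow(m), 5L, dimnames = list(NULL, 0:4))
  prob[, object$classes + 1L] <- prob_sub
  if (type == "prob") return(prob)
  as.integer(max.col(prob, ties.method = "first") - 1L)
}

#' @export
print.base_classifier <- function(x, ...) {
  cat(sprintf("base_classifier: %s, classes {%s}\n", x$base,
              paste(x$classes, collapse = ", ")))
  invisible(x)
}
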