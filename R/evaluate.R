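#' Confusion matrix for 5-class predictions
#'
#' @param y_true,y_pred Integer label vectors in `0..n_classes-1`.
#' @param n_classes Number of classes (default 5).
#' @return Integer `n_classes` x `n_classes` matrix; entry `(i, j)` counts
#'   samples of true class `i-1` predicted as class `j-1`.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes = 5L) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred lengths differ")
  if (any(c(y_true, y_pred) < 0L) || any(c(y_true, y_pred) >= n_classes))
    stop("labels out of range 0..", n_classes - 1L)
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(true = 0:(n_classes - 1L),
                               predicted = 0:(n_classes - 1L)))
  for (i in seq_along(y_true))
    cm[y_true[i] + 1L, y_pred[i] + 1L] <- cm[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  cm
}

#' Per-class precision and recall from a confusion matrix
#'
#' `precision_i = TP_i / (TP_i + FP_i)` (column-wise) and
#' `recall_i = TP_i / (TP_i + FN_i)` (row-wise). A class that is never
#' predicted (or never occurs) has an empty denominator; its score is
#' defined as 0 and flagged, so weighted sums stay finite.
#'
#' @param confusion Square count matrix, rows = true, columns = predicted.
#' @return List with `precision`, `recall` and logical `flagged` (classes
#'   with an empty denominator in either score).
#' @export
precision_recall <- function(confusion) {
  confusion <- as.matrix(confusion)
  tp <- diag(confusion)
  colsum <- colSums(confusion); rowsum <- rowSums(confusion)
  precision <- ifelse(colsum > 0, tp / colsum, 0)
  recall <- ifelse(rowsum > 0, tp / rowsum, 0)
  list(precision = as.numeric(precision), recall = as.numeric(recall),
       flagged = colsum == 0 | rowsum == 0)
}

#' Macro and weighted summary metrics
#'
#' Three summary scores over the five status classes: macro averaged
#' precision (MAP, the unweighted mean of per-class precisions), weighted
#' averaged precision (WAP) and weighted recall (WR), where the weights
#' `alpha_i` are the true-class shares `C_i / sum(C)`. WR is algebraically
#' identical to the overall (micro) accuracy `trace / total`.
#'
#' @param confusion Square count matrix, rows = true, columns = predicted.
#' @return Named list `MAP`, `WAP`, `WR` (fractions in `[0, 1]`) plus
#'   `alpha` (class-share weights).
#' @export
summary_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  pr <- precision_recall(confusion)
  k1 <- nrow(confusion)
  alpha <- rowSums(confusion) / sum(confusion)
  list(MAP = sum(pr$precision) / k1,
       WAP = sum(alpha * pr$precision),
       WR = sum(alpha * pr$recall),
       alpha = as.numeric(alpha))
}

#' Full metrics report for a prediction set
#'
#' @param y_true,y_pred Integer labels 0--4.
#' @return A `metrics_report`: confusion matrix, per-class precision/recall,
#'   MAP/WAP/WR, class weights and the test-set imbalance ratio.
#' @export
metrics_report <- function(y_true, y_pred) {
  cm <- confusion_matrix(y_true, y_pred)
  pr <- precision_recall(cm)
  sm <- summary_metrics(cm)
  structure(list(confusion = cm, per_class_precision = pr$precision,
                 per_class_recall = pr$recall, flagged = pr$flagged,
                 MAP = sm$MAP, WAP = sm$WAP, WR = sm$WR, alpha = sm$alpha,
                 mu_testset = imbalance_ratio(y_true)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report: MAP %.1f%%  WAP %.1f%%  WR %.1f%%  (test mu = %.2f)\n",
              100 * x$MAP, 100 * x$WAP, 100 * x$WR, x$mu_testset))
  cat("confusion (rows = true, cols = predicted):\n")
  print(x$confusion)
  invisible(x)
}

#' Balanced test set by mean (down-)sampling
#'
#' Downsamples every class, without replacement, to the smallest class
#' count, producing a test set with `mu = 1` for class-fair evaluation.
#'
#' @param test A [labeled_set()]; every class must be non-empty.
#' @param seed Integer seed.
#' @return A balanced [labeled_set()].
#' @export
balance_test_set <- function(test, seed = 1L) {
  stopifnot(inherits(test, "labeled_set"))
  cnt <- class_counts(test)
  if (any(cnt == 0L))
    stop("class ", paste(which(cnt == 0L) - 1L, collapse = ", "),
         " is empty: cannot balance")
  n_min <- min(cnt)
  set.seed(seed)
  keep <- unlist(lapply(0:4, function(cls) {
    rows <- which(test$labels == cls)
    sort(rows[sample.int(length(rows), n_min)])
  }))
  labeled_set(test$spectra[keep, ], test$labels[keep],
              test$concentrations[keep])
}

#' Cross-validated WAP of the self-training pipeline
#'
#' Stratified k-fold cross-validation: each fold's held-out labeled samples
#' are scored with the WAP of a model self-trained on the remaining folds
#' plus the unlabeled pool.
#'
#' @param labeled A [labeled_set()].
#' @param unlabeled A [spectrum_matrix()] pool (pass a 0-row matrix, or
#'   `tau > 1`, for the supervised baseline).
#' @param folds Number of folds (>= 2).
#' @param seed Integer seed for the fold assignment.
#' @param ... Arguments for [self_train()].
#' @return List with `mean_wap` and the per-fold `wap` vector.
#' @export
cross_validate <- function(labeled, unlabeled, folds = 5L, seed = 1L, ...) {
  stopifnot(inherits(labeled, "labeled_set"), folds >= 2L)
  n <- nrow(labeled$spectra)
  set.seed(seed)
  fold <- integer(n)
  for (cls in unique(labeled$labels)) {
    rows <- which(labeled$labels == cls)
    fold[rows] <- sample(rep_len(seq_len(folds), length(rows)))
  }
  wap <- vapply(seq_len(folds), function(f) {
    tr <- fold != f
    fit <- self_train(labeled$spectra[tr, ], labeled$labels[tr],
                      unlabeled = unlabeled, seed = seed + f, ...)
    pred <- predict(fit, labeled$spectra[!tr, ])
    summary_metrics(confusion_matrix(labeled$labels[!tr], pred))$WAP
  }, numeric(1))
  list(mean_wap = mean(wap), wap = wap)
}

# Gini index of a node from class proportions, written as the pairwise
# product sum over distinct classes (equal to 1 - sum(p^2))
gini_index <- function(p) {
  sum(outer(p, p)) - sum(p * p)
}

# route training samples through one randomForest tree and accumulate the
# per-variable impurity decrease
tree_importance <- function(tree, x, y, n_classes, weighted) {
  imp <- numeric(ncol(x))
  recurse <- function(node, rows) {
    if (tree[node, "status"] == -1L || length(rows) == 0L) return()
    v <- tree[node, "split var"]
    sp <- tree[node, "split point"]
    left <- rows[x[rows, v] <= sp]
    right <- setdiff(rows, left)
    p_q <- tabulate(y[rows] + 1L, n_classes) / length(rows)
    g_q <- gini_index(p_q)
    g_l <- if (length(left)) gini_index(tabulate(y[left] + 1L, n_classes) /
                                          length(left)) else 0
    g_r <- if (length(right)) gini_index(tabulate(y[right] + 1L, n_classes) /
                                           length(right)) else 0
    dec <- if (weighted) {
      g_q - (length(left) / length(rows)) * g_l -
        (length(right) / length(rows)) * g_r
    } else {
      g_q - g_l - g_r
    }
    imp[v] <<- imp[v] + dec
    recurse(tree[node, "left daughter"], left)
    recurse(tree[node, "right daughter"], right)
  }
  recurse(1L, seq_len(nrow(x)))
  imp
}

#' Gini wavelength importance
#'
#' Ranks bands by the total Gini-impurity decrease they produce across all
#' splits of a random forest: for a split of node q into children i and j,
#' the default "weighted" mode accumulates
#' `G_q - (n_i/n_q) G_i - (n_j/n_q) G_j` (the standard non-negative
#' convention), while mode "literal" accumulates the unweighted difference
#' `G_q - G_i - G_j`, which can go negative. Node impurities are recomputed
#' by routing the training spectra through each stored tree. For a PLS-DA or
#' LDA model an auxiliary seeded forest is fitted on the model's training
#' data first.
#'
#' @param model A [fit_base()] or [self_train()] model.
#' @param mode "weighted" or "literal".
#' @param ntree Trees for the auxiliary forest (non-forest models only).
#' @param seed Seed for the auxiliary forest.
#' @return An `importance_profile`: list with `gini` (per-band, normalized
#'   to sum 1), `top_bands` (band indices ranked by importance) and `mode`.
#' @export
gini_importance <- function(model, mode = c("weighted", "literal"),
                            ntree = 200L, seed = 1L) {
  mode <- match.arg(mode)
  if (inherits(model, "self_train")) model <- model$model
  stopifnot(inherits(model, "base_classifier"))
  if (is.null(model$train_x))
    stop("model was fitted with keep_data = FALSE: cannot compute importance")
  x <- model$train_x; y <- model$train_y
  rf <- if (model$base == "rfc") model$fit else {
    set.seed(seed)
    randomForest::randomForest(x, factor(y), ntree = ntree)
  }
  n_classes <- length(unique(y))
  ymap <- match(y, sort(unique(y))) - 1L
  imp <- numeric(ncol(x))
  for (t in seq_len(rf$ntree)) {
    tr <- randomForest::getTree(rf, t, labelVar = FALSE)
    imp <- imp + tree_importance(tr, x, ymap, n_classes, mode == "weighted")
  }
  total <- sum(imp)
  if (total != 0) imp <- imp / total
  structure(list(gini = imp, top_bands = order(imp, decreasing = TRUE),
                 mode = mode),
            class = "importance_profile")
}

#' @export
print.importance_profile <- function(x, ...) {
  cat(sprintf("importance_profile (%s Gini): top bands %s\n", x$mode,
              paste(utils::head(x$top_bands, 5), collapse = ", ")))
  invisible(x)
}

#' Per-band Pearson correlation with element concentration
#'
#' @param spectra A [spectrum_matrix()].
#' @param conc Measured concentrations, one per row; must vary.
#' @return Numeric per-band correlation vector in `[-1, 1]`; constant bands
#'   get `r = 0` and are reported in attribute `flagged`.
#' @export
band_element_correlation <- function(spectra, conc) {
  m <- unclass(spectra)
  if (nrow(m) < 3L) stop("need at least 3 samples")
  if (stats::sd(conc) == 0) stop("concentration vector is constant")
  sds <- apply(m, 2, stats::sd)
  r <- numeric(ncol(m))
  ok <- sds > 0
  r[ok] <- as.numeric(stats::cor(m[, ok, drop = FALSE], conc))
  attr(r, "flagged") <- which(!ok)
  r
}
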