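#' Subsample the unlabeled pool to a labeled:unlabeled ratio
#'
#' The ratio `beta = D_labeled / D_unlabeled` controls how much unlabeled
#' data is injected: the quota is `round(n_labeled / beta)` pixels, drawn
#' without replacement. Typical settings are 1/2, 1/4, 1/6, 1/8. When the
#' pool is smaller than the quota the whole pool is returned with a warning.
#'
#' @param pool A [spectrum_matrix()] of screened unlabeled pixels.
#' @param beta Positive ratio of labeled to injected unlabeled samples.
#' @param n_labeled Number of labeled samples.
#' @param seed Integer seed.
#' @return A [spectrum_matrix()] of the injected pixels.
#' @export
subsample_unlabeled <- function(pool, beta, n_labeled, seed = 1L) {
  if (beta <= 0) stop("beta must be positive")
  n_pool <- nrow(pool)
  if (n_pool < 1L) stop("empty unlabeled pool")
  quota <- round(n_labeled / beta)
  if (quota >= n_pool) {
    if (quota > n_pool)
      warning("unlabeled pool (", n_pool, ") smaller than quota (", quota,
              "): using the whole pool")
    return(pool)
  }
  set.seed(seed)
  pool[sample.int(n_pool, quota), , drop = FALSE]
}

#' Pseudo-label unlabeled spectra at a confidence threshold
#'
#' Predicts class probabilities for every unlabeled sample and keeps those
#' whose maximum class probability reaches `tau`; the pseudo-label is the
#' argmax class (ties toward the lowest class index). An empty selection is
#' allowed.
#'
#' @param model A [fit_base()] classifier.
#' @param u Unlabeled spectra on the model's band grid.
#' @param tau Confidence threshold in `(0, 1]` (values above 1 select
#'   nothing).
#' @return List with `idx` (row indices kept), `x` (their spectra),
#'   `labels` (pseudo-labels) and `conf` (their confidences).
#' @export
pseudo_label <- function(model, u, tau) {
  prob <- stats::predict(model, u, type = "prob")
  conf <- apply(prob, 1, max)
  y_hat <- as.integer(max.col(prob, ties.method = "first") - 1L)
  idx <- which(conf >= tau)
  list(idx = idx, x = unclass(u)[idx, , drop = FALSE],
       labels = y_hat[idx], conf = conf[idx], all_labels = y_hat)
}

#' Class-rebalanced self-training
#'
#' The core fitting procedure: a base classifier is trained on the (optionally
#' SMOTE-balanced) labeled spectra, predicts the injected unlabeled pixels,
#' and its high-confidence pseudo-labels are resampled by the chosen scheme
#' to control class balance; the classifier is then refit on labeled plus
#' rebalanced pseudo data, iterating until the pseudo-labels stabilize.
#'
#' Per-iteration bookkeeping (pseudo-class counts, the imbalance ratio mu of
#' the rebalanced pseudo set, high-confidence counts, label-change fraction)
#' is recorded in the returned object's `history`; with the "mes" or "smote"
#' pseudo-sampler every recorded mu equals 1 by construction, while "res"
#' drives mu down gradually and "ras" tracks the skew of the
#' high-confidence pool.
#'
#' @param x Labeled spectra: a [spectrum_matrix()] or a [labeled_set()] (in
#'   which case `y` is taken from it).
#' @param y Integer class labels 0--4.
#' @param unlabeled A [spectrum_matrix()] of screened unlabeled pixels (the
#'   pool; the injected subset is controlled by `beta`).
#' @param base Base classifier: "plsda", "lda" or "rfc".
#' @param beta Labeled:unlabeled ratio for [subsample_unlabeled()].
#' @param tau Pseudo-label confidence threshold; `tau > 1` accepts nothing
#'   and reproduces the supervised fit.
#' @param max_iter Maximum self-training iterations; 0 gives the plain
#'   supervised fit.
#' @param labeled_sampler "none" or "smote": one-off balancing of the
#'   labeled data before the loop.
#' @param pseudo_sampler "ras", "mes", "smote" or "res": per-iteration
#'   rebalancing of the high-confidence pseudo set.
#' @param pseudo_budget Pseudo samples drawn per iteration; default one
#'   labeled-set-worth (capped by the high-confidence count; for "mes"
#'   rounded down to a multiple of the number of classes so mu stays exactly
#'   1).
#' @param stop_eps Convergence: stop when the fraction of unlabeled samples
#'   whose pseudo-label changed since the previous iteration falls below
#'   this.
#' @param seed Integer seed; the whole procedure is a deterministic function
#'   of its inputs and the seed.
#' @param ... Extra arguments for [fit_base()] (e.g. `ncomp`, `ntree`).
#' @return An object of class `self_train`; see
#'   [predict.self_train()], [summary.self_train()], [plot.self_train()].
#' @export
self_train <- function(x, y = NULL, unlabeled, base = c("rfc", "plsda", "lda"),
                       beta = 1 / 4, tau = 0.8, max_iter = 10L,
                       labeled_sampler = c("none", "smote"),
                       pseudo_sampler = c("mes", "ras", "smote", "res"),
                       pseudo_budget = NULL, stop_eps = 0.01, seed = 1L,
                       ...) {
  if (inherits(x, "labeled_set")) { y <- x$labels; x <- x$spectra }
  base <- match.arg(tolower(base), c("rfc", "plsda", "lda"))
  labeled_sampler <- match.arg(tolower(labeled_sampler), c("none", "smote"))
  pseudo_sampler <- match.arg(tolower(pseudo_sampler),
                              c("mes", "ras", "smote", "res"))
  if (tau <= 0) stop("tau must be positive")
  if (max_iter < 0L) stop("max_iter must be non-negative")
  if (labeled_sampler == "smote" && pseudo_sampler == "res")
    warning("reverse sampling is designed to start from the raw skewed ",
            "labeled data; pairing it with SMOTE-balanced labeled data ",
            "is not the studied configuration")
  seed <- as.integer(seed)
  m <- unclass(x); y <- as.integer(y)
  if (nrow(m) == 0L) stop("empty labeled set")

  # one-off balancing of the labeled data
  if (labeled_sampler == "smote") {
    bal <- resample_set(m, y, sampler_spec("smote", seed = seed + 101L))
    Lx <- bal$x; Ly <- bal$labels
  } else {
    Lx <- m; Ly <- y
  }

  # injected unlabeled pool: beta counts the original labeled size
  U <- subsample_unlabeled(unlabeled, beta, nrow(m), seed = seed + 202L)

  fit_seed <- seed + 303L
  model <- fit_base(base, Lx, Ly, seed = fit_seed, ...)
  history <- data.frame()
  prev_labels <- NULL
  converged <- FALSE
  n_empty <- 0L
  Px <- NULL; Py <- integer(0)

  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    train_x <- if (is.null(Px)) Lx else rbind(Lx, Px)
    train_y <- c(Ly, Py)
    model <- fit_base(base, train_x, train_y, seed = fit_seed, ...)
    pl <- pseudo_label(model, U, tau)
    n_hc <- length(pl$idx)
    changed <- if (is.null(prev_labels)) NA_real_ else
      mean(pl$all_labels != prev_labels)
    prev_labels <- pl$all_labels

    if (n_hc == 0L) {
      n_empty <- n_empty + 1L
      history <- rbind(history, data.frame(
        iteration = iter, n_high_confidence = 0L, n_pseudo = 0L,
        mu = NA_real_, changed_frac = changed,
        t(stats::setNames(rep(0L, 5L), paste0("count_", 0:4)))))
      if (n_empty >= 3L) {
        warning("no high-confidence pseudo-labels for 3 consecutive ",
                "iterations: returning the supervised model")
        model <- fit_base(base, Lx, Ly, seed = fit_seed, ...)
        break
      }
      Px <- NULL; Py <- integer(0)
      next
    }
    n_empty <- 0L

    budget <- if (is.null(pseudo_budget)) nrow(Lx) else pseudo_budget
    budget <- min(budget, n_hc)
    if (pseudo_sampler == "mes") {
      k_live <- length(unique(pl$labels))
      budget <- max(k_live, k_live * (budget %/% k_live))
    }
    rs <- resample_set(pl$x, pl$labels,
                       sampler_spec(pseudo_sampler, target_n = budget,
                                    seed = seed + 404L + iter))
    Px <- rs$x; Py <- rs$labels
    cnt <- class_counts(Py)
    history <- rbind(history, data.frame(
      iteration = iter, n_high_confidence = n_hc, n_pseudo = length(Py),
      mu = imbalance_ratio(cnt, counts = TRUE), changed_frac = changed,
      t(stats::setNames(cnt, paste0("count_", 0:4)))))

    if (!is.na(changed) && changed < stop_eps) { converged <- TRUE; break }
  }

  # final refit so the returned classifier has seen the last rebalanced
  # pseudo set; with no accepted pseudo data this is exactly the supervised fit
  if (max_iter == 0L || n_empty < 3L) {
    train_x <- if (length(Py) > 0L) rbind(Lx, Px) else Lx
    model <- fit_base(base, train_x, c(Ly, Py), seed = fit_seed, ...)
  }

  structure(list(
    model = model, base = base,
    config = list(base = base, beta = beta, tau = tau, max_iter = max_iter,
                  labeled_sampler = labeled_sampler,
                  pseudo_sampler = pseudo_sampler, stop_eps = stop_eps,
                  seed = seed),
    history = history, converged = converged,
    n_labeled = nrow(m), n_labeled_balanced = nrow(Lx),
    n_unlabeled = nrow(U),
    mu_labeled = imbalance_ratio(y),
    wavelengths = attr(x, "wavelengths")),
    class = "self_train")
}

#' @export
print.self_train <- function(x, ...) {
  cat("Class-rebalanced self-training model\n")
  cat(sprintf("  base classifier : %s\n", x$base))
  cat(sprintf("  labeled samples : %d (mu = %.2f%s)\n", x$n_labeled,
              x$mu_labeled,
              if (x$config$labeled_sampler == "smote")
                sprintf("; SMOTE-balanced to %d", x$n_labeled_balanced)
              else ""))
  cat(sprintf("  unlabeled used  : %d (beta = %.3g)\n", x$n_unlabeled,
              x$config$beta))
  cat(sprintf("  pseudo sampler  : %s, tau = %.2f\n",
              toupper(x$config$pseudo_sampler), x$config$tau))
  cat(sprintf("  iterations      : %d (%s)\n", nrow(x$history),
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' Summarize a self-training run
#'
#' @param object A [self_train()] model.
#' @param ... Unused.
#' @return The per-iteration history data frame (pseudo-class counts, mu
#'   trajectory, label-change fraction), invisibly printed.
#' @export
summary.self_train <- function(object, ...) {
  print(object)
  if (nrow(object$history) > 0L) {
    cat("\nPer-iteration history:\n")
    print(object$history, row.names = FALSE)
  }
  invisible(object$history)
}

#' @export
predict.self_train <- function(object, newdata, type = c("class", "prob"),
                               ...) {
  stats::predict(object$model, newdata, type = match.arg(type))
}

#' Plot the rebalancing trajectory of a self-training run
#'
#' Left panel: per-iteration pseudo-label class counts (stacked bars);
#' right panel: the imbalance ratio mu of the rebalanced pseudo set.
#'
#' @param x A [self_train()] model.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.self_train <- function(x, ...) {
  h <- x$history
  if (nrow(h) == 0L) {
    warning("no iterations recorded: nothing to plot")
    return(invisible(x))
  }
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  cnts <- t(as.matrix(h[, paste0("count_", 0:4)]))
  graphics::barplot(cnts, names.arg = h$iteration,
                    xlab = "iteration", ylab = "pseudo-label count",
                    legend.text = c("VL", "Low", "Proper", "High", "VH"),
                    ...)
  graphics::plot(h$iteration, h$mu, type = "b", xlab = "iteration",
                 ylab = expression(mu), ylim = c(1, max(h$mu, na.rm = TRUE)))
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}
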