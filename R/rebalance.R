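#' Class imbalance ratio
#'
#' The ratio of the largest to the smallest non-empty class count,
#' `mu = C_max / C_min`; `mu = 1` is perfectly balanced. The K-training
#' division of the rubber-leaf study (29:131:185:289:116) has `mu = 9.97`.
#'
#' @param x Integer label vector (0-based classes), a `labeled_set`, or a
#'   vector of per-class counts when `counts = TRUE`.
#' @param counts Interpret `x` directly as per-class counts.
#' @return The imbalance ratio, a number `>= 1`.
#' @examples
#' imbalance_ratio(c(29, 131, 185, 289, 116), counts = TRUE)  # 9.97
#' @export
imbalance_ratio <- function(x, counts = FALSE) {
  cnt <- if (counts) as.numeric(x) else class_counts(x)
  cnt <- cnt[cnt > 0]
  if (length(cnt) == 0L) stop("no samples: imbalance ratio undefined")
  max(cnt) / min(cnt)
}

#' Per-class selection probabilities of the resampling schemes
#'
#' The three probability-based schemes select which class to draw from:
#' random sampling (RAS) keeps the empirical distribution, `p_j`
#' proportional to the class count `C_j`; mean sampling (MES) gives every
#' class the equal probability `1/k`; reverse sampling (RES) inverts the
#' frequencies, `p_j` proportional to `1/C_j`, favoring minority classes.
#' Empty classes receive probability 0 and the remainder is renormalized.
#'
#' @param method "ras", "mes" or "res".
#' @param counts Non-negative per-class counts.
#' @return Probability vector summing to 1.
#' @examples
#' class_probabilities("res", c(1, 4))  # 0.8 0.2
#' @export
class_probabilities <- function(method = c("ras", "mes", "res"), counts) {
  method <- match.arg(tolower(method), c("ras", "mes", "res"))
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("negative class count")
  live <- counts > 0
  if (!any(live)) stop("all classes empty")
  w <- numeric(length(counts))
  w[live] <- switch(method,
                    ras = counts[live],
                    mes = 1,
                    res = 1 / counts[live])
  w / sum(w)
}

#' Resampling-scheme specification
#'
#' @param method One of "ras", "mes", "smote", "res", or "none".
#' @param target_n Total number of samples to draw (RAS/RES) or to spread
#'   equally across classes (MES). Ignored by SMOTE, which always augments
#'   every minority class up to the majority count.
#' @param k_neighbors Number of nearest neighbours used by SMOTE.
#' @param seed Integer seed.
#' @return A `sampler_spec` object.
#' @export
sampler_spec <- function(method = c("ras", "mes", "smote", "res", "none"),
                         target_n = NULL, k_neighbors = 5L, seed = 1L) {
  method <- match.arg(tolower(method),
                      c("ras", "mes", "smote", "res", "none"))
  if (!is.null(target_n) && target_n <= 0) stop("target_n must be positive")
  if (k_neighbors < 1L) stop("k_neighbors must be at least 1")
  structure(list(method = method, target_n = target_n,
                 k_neighbors = as.integer(k_neighbors),
                 seed = as.integer(seed)),
            class = "sampler_spec")
}

#' Synthesize minority-class samples (SMOTE)
#'
#' Each synthetic sample is a convex combination `x_i + u (x_nn - x_i)` of a
#' minority sample and one of its `k_neighbors` nearest minority neighbours
#' (Euclidean distance), `u ~ Uniform(0, 1)`; every synthetic band value
#' therefore lies between its two parents' values.
#'
#' @param x_minority A [spectrum_matrix()] (or plain matrix) of minority
#'   samples, at least 2 rows.
#' @param n_new Number of synthetic samples to create.
#' @param k_neighbors Neighbourhood size; reduced with a warning when the
#'   class has at most `k_neighbors` samples.
#' @param seed Integer seed.
#' @return Matrix of `n_new` synthetic rows (same band grid).
#' @export
smote_synthesize <- function(x_minority, n_new, k_neighbors = 5L, seed = 1L) {
  if (k_neighbors < 1L) stop("k_neighbors must be at least 1")
  m <- unclass(x_minority)
  n <- nrow(m)
  if (n < 2L) stop("SMOTE needs at least 2 minority samples")
  if (n_new == 0L) return(m[integer(0), , drop = FALSE])
  if (n - 1L < k_neighbors) {
    warning("class has only ", n, " samples: reducing k_neighbors to ", n - 1L)
    k_neighbors <- n - 1L
  }
  d <- as.matrix(stats::dist(m))
  diag(d) <- Inf
  nn <- matrix(0L, n, k_neighbors)
  for (i in seq_len(n)) nn[i, ] <- order(d[i, ])[seq_len(k_neighbors)]
  set.seed(seed)
  base_i <- sample.int(n, n_new, replace = TRUE)
  nbr_j <- nn[cbind(base_i, sample.int(k_neighbors, n_new, replace = TRUE))]
  u <- stats::runif(n_new)
  m[base_i, , drop = FALSE] + u * (m[nbr_j, , drop = FALSE] -
                                     m[base_i, , drop = FALSE])
}

#' Resample a labeled spectral set to control class balance
#'
#' The workhorse of the per-iteration rebalancing step. RAS and RES draw
#' `target_n` samples by first picking a class from
#' [class_probabilities()] and then drawing uniformly with replacement
#' within it. MES draws exactly `floor(target_n / k)` samples per non-empty
#' class, allocating the remainder to the smallest classes first, so the
#' output has `mu = 1` (up to the remainder). SMOTE augments every minority
#' class with synthetic samples up to the majority count (`mu = 1` exactly);
#' a single-sample class falls back to duplication with a warning. The
#' output row order is shuffled by the seed.
#'
#' @param x A [spectrum_matrix()] or plain matrix of samples.
#' @param labels Integer class labels 0--4, one per row.
#' @param spec A [sampler_spec()].
#' @return List with elements `x` (matrix of drawn rows), `labels`, and
#'   `synthetic` (logical; TRUE for SMOTE-generated rows).
#' @export
resample_set <- function(x, labels, spec) {
  stopifnot(inherits(spec, "sampler_spec"))
  m <- unclass(x)
  labels <- as.integer(labels)
  if (nrow(m) == 0L) stop("empty input")
  if (spec$method == "none")
    return(list(x = m, labels = labels, synthetic = rep(FALSE, nrow(m))))
  cnt <- class_counts(labels)
  classes <- which(cnt > 0L) - 1L
  set.seed(spec$seed)

  if (spec$method == "smote") {
    maj <- max(cnt[cnt > 0])
    out_x <- m; out_y <- labels
    syn <- rep(FALSE, nrow(m))
    for (cls in classes) {
      need <- maj - cnt[cls + 1L]
      if (need == 0L) next
      rows <- which(labels == cls)
      if (length(rows) < 2L) {
        warning("class ", cls,
                " has a single sample: SMOTE falls back to duplication")
        new <- m[rep(rows, need), , drop = FALSE]
      } else {
        new <- smote_synthesize(m[rows, , drop = FALSE], need,
                                spec$k_neighbors,
                                seed = spec$seed + cls + 1L)
      }
      out_x <- rbind(out_x, new)
      out_y <- c(out_y, rep(cls, need))
      syn <- c(syn, rep(TRUE, need))
    }
    set.seed(spec$seed)
    ord <- sample.int(length(out_y))
    return(list(x = out_x[ord, , drop = FALSE], labels = out_y[ord],
                synthetic = syn[ord]))
  }

  target_n <- spec$target_n
  if (is.null(target_n)) target_n <- nrow(m)

  if (spec$method == "mes") {
    k <- length(classes)
    per <- rep(target_n %/% k, k)
    rem <- target_n %% k
    if (rem > 0L) {
      # remainder to the smallest classes first (stable in class index)
      ord_small <- order(cnt[classes + 1L], classes)
      per[ord_small[seq_len(rem)]] <- per[ord_small[seq_len(rem)]] + 1L
    }
    draw <- unlist(lapply(seq_along(classes), function(i) {
      rows <- which(labels == classes[i])
      rows[sample.int(length(rows), per[i], replace = TRUE)]
    }))
  } else {
    p <- class_probabilities(spec$method, cnt)
    drawn_cls <- sample(0:4, target_n, replace = TRUE, prob = p)
    draw <- vapply(drawn_cls, function(cls) {
      rows <- which(labels == cls)
      rows[sample.int(length(rows), 1L)]
    }, integer(1))
  }
  ord <- sample.int(length(draw))
  draw <- draw[ord]
  list(x = m[draw, , drop = FALSE], labels = labels[draw],
       synthetic = rep(FALSE, length(draw)))
}
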