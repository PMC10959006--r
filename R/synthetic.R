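#' Specification for the synthetic spectra generator
#'
#' Describes the statistical structure of a synthetic labeled NIR leaf data
#' set: five status classes with a chosen (typically imbalanced) count
#' profile, a smooth shared reflectance archetype, class-conditional bumps
#' planted inside informative wavelength windows, per-sample multiplicative
#' scatter, additive band noise, and a narrow high-variance artifact band
#' near 1380 nm. Defaults emulate the nitrogen study conditions: the
#' training-division counts 45:93:225:104:268 and the nitrogen-informative
#' windows 945--980, 1548--1592 and 1651--1680 nm.
#'
#' @param scheme A [class_scheme()]; controls the concentration intervals
#'   sampled per class.
#' @param class_counts Integer 5-vector of per-class sample counts.
#' @param informative_windows List of `c(lo, hi)` nm intervals carrying the
#'   class signal.
#' @param effect_size Separation of adjacent class mean responses inside the
#'   informative windows, in units of `noise_sd`.
#' @param noise_sd Additive per-band noise SD (reflectance units).
#' @param scatter_sd SD of the per-sample multiplicative scatter factor.
#' @param artifact_nm Center of the single-band high-variance noise spike.
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return A `generator_spec` object.
#' @export
generator_spec <- function(scheme = class_scheme("N"),
                           class_counts = c(45L, 93L, 225L, 104L, 268L),
                           informative_windows = list(c(945, 980),
                                                      c(1548, 1592),
                                                      c(1651, 1680)),
                           effect_size = 0.8,
                           noise_sd = 0.012,
                           scatter_sd = 0.02,
                           artifact_nm = 1380,
                           seed = 1L) {
  stopifnot(length(class_counts) == 5L, all(class_counts >= 0L),
            any(class_counts > 0L), effect_size >= 0, noise_sd > 0,
            scatter_sd >= 0)
  structure(list(scheme = scheme, class_counts = as.integer(class_counts),
                 informative_windows = informative_windows,
                 effect_size = effect_size, noise_sd = noise_sd,
                 scatter_sd = scatter_sd, artifact_nm = artifact_nm,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

# smooth leaf-reflectance archetype: broad NIR plateau with water-absorption
# dips near 1200 and 1450 nm, interpolated from fixed control points
leaf_archetype <- function(wl) {
  ctrl_wl <- c(900, 1000, 1100, 1200, 1300, 1380, 1450, 1550, 1650, 1700)
  ctrl_r  <- c(0.52, 0.55, 0.56, 0.50, 0.53, 0.48, 0.36, 0.42, 0.40, 0.38)
  stats::spline(ctrl_wl, ctrl_r, xout = wl)$y
}

# per-class mean deviation: one smooth Gaussian bump per informative window.
# Successive windows carry different class contrasts (linear, quadratic,
# alternating in the class index) so the five class means span several
# spectral directions rather than a single line; adjacent classes differ by
# about effect_size * noise_sd at the window centers.
class_mean_curves <- function(spec, wl) {
  base <- leaf_archetype(wl)
  step <- spec$effect_size * spec$noise_sd
  # orthogonal polynomial contrasts over the 5 ordered status levels: every
  # pair of classes differs in at least two windows
  contrasts <- t(stats::contr.poly(5)) * 3
  curves <- matrix(rep(base, 5L), nrow = 5L, byrow = TRUE)
  for (wi in seq_along(spec$informative_windows)) {
    w <- spec$informative_windows[[wi]]
    ctr <- mean(w); width <- (w[2] - w[1]) / 4
    bump <- exp(-((wl - ctr)^2) / (2 * width^2))
    amp <- contrasts[(wi - 1L) %% 3L + 1L, ]
    for (cls in 0:4) curves[cls + 1L, ] <-
        curves[cls + 1L, ] + amp[cls + 1L] * step * bump
  }
  curves
}

# concentration interval per class; open-ended outer classes extended by the
# width of the neighbouring interval
class_conc_intervals <- function(scheme) {
  th <- scheme$thresholds
  lo <- c(th[1] - (th[2] - th[1]), th[1], th[2], th[3], th[4])
  hi <- c(th[1], th[2], th[3], th[4], th[4] + (th[4] - th[3]))
  cbind(lo, hi)
}

#' Simulate a labeled set of leaf mean spectra
#'
#' Each sample is the shared smooth archetype plus its class's planted bumps,
#' scaled by a multiplicative scatter factor `1 + e`, `e ~ N(0, scatter_sd)`,
#' plus additive `N(0, noise_sd)` band noise and a `10 * noise_sd` noise
#' spike in the band nearest `artifact_nm`. Concentrations are drawn
#' uniformly within each class's scheme interval (outer classes use a bounded
#' extension of the adjacent interval's width).
#'
#' @param spec A [generator_spec()].
#' @param wl Wavelength grid (default the trimmed 224-band grid).
#' @return A [labeled_set()] with concentrations; rows are shuffled.
#' @export
simulate_labeled_set <- function(spec, wl = default_wavelength_grid()) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  n <- sum(spec$class_counts)
  labels <- rep(0:4, times = spec$class_counts)
  curves <- class_mean_curves(spec, wl)
  ab <- which.min(abs(wl - spec$artifact_nm))
  X <- matrix(0, n, length(wl))
  for (i in seq_len(n)) {
    scatter <- 1 + stats::rnorm(1, 0, spec$scatter_sd)
    X[i, ] <- curves[labels[i] + 1L, ] * scatter +
      stats::rnorm(length(wl), 0, spec$noise_sd)
  }
  X[, ab] <- X[, ab] + stats::rnorm(n, 0, 10 * spec$noise_sd)
  iv <- class_conc_intervals(spec$scheme)
  conc <- stats::runif(n, iv[labels + 1L, 1], iv[labels + 1L, 2])
  ord <- sample.int(n)
  labeled_set(spectrum_matrix(X[ord, , drop = FALSE], wl), labels[ord],
              conc[ord], spec$scheme)
}

#' Simulate a hyperspectral leaf cube
#'
#' Generates an elliptical leaf on an H x W canvas for one status class. Vein
#' pixels (a midrib plus lateral branches) track the leaf's mean spectrum
#' closely: slightly brighter, with low pixel noise. Lamina pixels are
#' attenuated in albedo, carry stronger pixel noise and a spatially
#' correlated multiplicative scatter field (separable moving-average of white
#' noise). The vein/lamina gains are weighted by `vein_fraction` so the mean
#' spectrum over the leaf mask converges to the generating class mean as the
#' canvas grows.
#'
#' @param spec A [generator_spec()] (its noise/scatter scales and seed are
#'   used; the class signal comes from `class_label`).
#' @param height,width Canvas size in pixels.
#' @param class_label Status class 0--4 generating the leaf.
#' @param vein_fraction Approximate fraction of leaf pixels that are vein;
#'   must lie in (0, 1).
#' @param wl Wavelength grid.
#' @return An [hsi_cube()].
#' @export
simulate_leaf_cube <- function(spec, height = 40L, width = 40L,
                               class_label = 2L, vein_fraction = 0.2,
                               wl = default_wavelength_grid()) {
  stopifnot(inherits(spec, "generator_spec"),
            vein_fraction > 0, vein_fraction < 1)
  set.seed(spec$seed + 7L)
  H <- as.integer(height); W <- as.integer(width)
  rowc <- (seq_len(H) - (H + 1) / 2) / (H / 2)
  colc <- (seq_len(W) - (W + 1) / 2) / (W / 2)
  leaf <- outer(rowc^2 / 0.9^2, colc^2 / 0.75^2, `+`) <= 1
  if (!any(leaf)) stop("degenerate canvas: empty leaf mask")

  # midrib along the long axis + lateral veins, dilated until the requested
  # vein fraction is reached
  vein <- matrix(FALSE, H, W)
  mid <- round((W + 1) / 2)
  vein[, mid] <- TRUE
  for (r in seq(3, H - 2, by = max(2L, H %/% 8L)))
    for (k in 0:max(H, W)) {
      cc <- c(mid - k, mid + k); rr <- r + k
      if (rr > H) break
      cc <- cc[cc >= 1 & cc <= W]
      vein[rr, cc] <- TRUE
    }
  vein <- vein & leaf
  while (sum(vein) < vein_fraction * sum(leaf)) {
    grown <- vein
    grown[-1, ] <- grown[-1, ] | vein[-H, ]
    grown[, -1] <- grown[, -1] | vein[, -W]
    if (identical(grown & leaf, vein)) break
    vein <- grown & leaf
  }

  q <- class_mean_curves(spec, wl)[class_label + 1L, ]
  vf <- sum(vein) / sum(leaf)
  vein_gain <- 1.04
  lamina_gain <- (1 - vf * vein_gain) / (1 - vf)

  # spatially correlated scatter field: separable moving average of white
  # noise, rescaled to scatter_sd
  ma <- function(m, k = 3L) {
    out <- m
    for (sh in seq_len(k)) {
      out[-seq_len(sh), ] <- out[-seq_len(sh), ] + m[seq_len(nrow(m) - sh), ]
      out[, -seq_len(sh)] <- out[, -seq_len(sh)] + m[, seq_len(ncol(m) - sh)]
    }
    out / (2 * k + 1)
  }
  field <- ma(matrix(stats::rnorm(H * W), H, W))
  field <- field / stats::sd(field) * spec$scatter_sd

  B <- length(wl)
  ab <- which.min(abs(wl - spec$artifact_nm))
  data <- array(0, dim = c(H, W, B))
  idx <- which(leaf, arr.ind = TRUE)
  for (p in seq_len(nrow(idx))) {
    r <- idx[p, 1]; cc <- idx[p, 2]
    if (vein[r, cc]) {
      px <- q * vein_gain * (1 + stats::rnorm(1, 0, spec$scatter_sd / 4)) +
        stats::rnorm(B, 0, spec$noise_sd / 2)
    } else {
      px <- q * lamina_gain * (1 + field[r, cc] +
                                 stats::rnorm(1, 0, spec$scatter_sd)) +
        stats::rnorm(B, 0, spec$noise_sd * 1.5)
    }
    px[ab] <- px[ab] + stats::rnorm(1, 0, 10 * spec$noise_sd)
    data[r, cc, ] <- px
  }
  hsi_cube(data, wl, leaf, vein)
}

#' Randomly divide a labeled set into train / validation / test
#'
#' Plain random (non-stratified) division at the given ratios, mirroring the
#' approximately 6:2:2 division of the study.
#'
#' @param labeled A [labeled_set()].
#' @param ratios Three non-negative fractions summing to 1.
#' @param seed Integer seed.
#' @return List of three `labeled_set`s: `train`, `validation`, `test`, with
#'   attribute `counts` recording per-split class counts.
#' @export
make_split <- function(labeled, ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(inherits(labeled, "labeled_set"), length(ratios) == 3L,
            all(ratios >= 0), abs(sum(ratios) - 1) < 1e-8)
  n <- nrow(labeled$spectra)
  if (n == 0L) stop("empty labeled set")
  set.seed(seed)
  ord <- sample.int(n)
  n_train <- round(ratios[1] * n)
  n_val <- round(ratios[2] * n)
  n_val <- min(n_val, n - n_train)
  take <- function(i) {
    if (length(i) == 0L)
      return(labeled_set(labeled$spectra[integer(0), ], integer(0),
                         labeled$concentrations[integer(0)]))
    labeled_set(labeled$spectra[i, ], labeled$labels[i],
                labeled$concentrations[i])
  }
  splits <- list(train = take(ord[seq_len(n_train)]),
                 validation = take(ord[seq_len(n_val) + n_train]),
                 test = take(ord[setdiff(seq_len(n), seq_len(n_train + n_val))]))
  attr(splits, "counts") <- lapply(splits, class_counts)
  splits
}
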