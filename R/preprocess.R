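#' Savitzky-Golay smoothing along the band axis
#'
#' Local least-squares polynomial smoothing of each spectrum, the standard
#' chemometric filter for suppressing narrow noise artifacts (such as the
#' single-band spike near 1380 nm) while preserving broad absorption
#' features. Polynomials of degree at most `polyorder` are reproduced
#' exactly. Defaults (window 11, order 2) suit the ~3.3 nm band spacing.
#'
#' @param spectra A [spectrum_matrix()], or a numeric vector treated as one
#'   spectrum.
#' @param window Odd window length in bands.
#' @param polyorder Polynomial order, strictly smaller than `window`.
#' @return Smoothed object of the same type; wavelengths unchanged.
#' @export
sg_smooth <- function(spectra, window = 11L, polyorder = 2L) {
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L) stop("window must be odd")
  if (polyorder >= window) stop("polyorder must be smaller than window")
  if (is.null(dim(spectra))) {
    return(as.numeric(signal::sgolayfilt(spectra, p = polyorder, n = window)))
  }
  stopifnot(inherits(spectra, "spectrum_matrix"))
  sm <- t(apply(unclass(spectra), 1,
                signal::sgolayfilt, p = polyorder, n = window))
  spectrum_matrix(sm, wavelengths(spectra))
}

#' Mean spectrum over a masked cube region
#'
#' @param cube An [hsi_cube()].
#' @param region "leaf" or "vein": which mask to average over.
#' @return Numeric per-band mean spectrum.
#' @export
mean_spectrum <- function(cube, region = c("leaf", "vein")) {
  stopifnot(inherits(cube, "hsi_cube"))
  region <- match.arg(region)
  mask <- if (region == "leaf") cube$leaf_mask else cube$vein_mask
  if (!any(mask)) stop("empty ", region, " mask")
  px <- cube_pixels(cube, mask)
  colMeans(unclass(px))
}

# masked pixels as a spectrum_matrix, rows in raster (column-major) order
cube_pixels <- function(cube, mask = cube$leaf_mask) {
  B <- dim(cube$data)[3]
  m <- matrix(cube$data, ncol = B)[as.vector(mask), , drop = FALSE]
  spectrum_matrix(m, cube$wavelengths)
}

#' Min-max normalization to [0, 1]
#'
#' Affine map sending the minimum to 0 and the maximum to 1; order
#' preserving. A constant vector has no span and is returned as all zeros
#' with a warning.
#'
#' @param x Numeric vector.
#' @return Numeric vector in `[0, 1]`.
#' @export
minmax_norm <- function(x) {
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning("constant vector: min-max normalization undefined, returning zeros")
    return(rep(0, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Similarity of unlabeled pixels to a reference mean spectrum
#'
#' Scores each pixel spectrum k_i against the labeled mean spectrum q as the
#' scaled dot product `(q . k_i) / d`, where d is the spectrum
#' dimensionality (224 on the trimmed grid), then min-max normalizes the
#' scores across pixels to `[0, 1]`. This is the screening statistic of the
#' rebalancing pipeline; note that, lacking a vector-norm denominator, it is
#' magnitude-sensitive. Set `cosine = TRUE` for the conventional
#' norm-invariant cosine similarity instead.
#'
#' @param q Reference spectrum (numeric vector).
#' @param pixels A [spectrum_matrix()] of pixel spectra on the same grid.
#' @param cosine Use true cosine similarity instead of the scaled dot
#'   product.
#' @return Numeric score vector in `[0, 1]`, one per pixel.
#' @export
pixel_similarity <- function(q, pixels, cosine = FALSE) {
  if (length(q) != ncol(pixels))
    stop("reference spectrum and pixels disagree on band count")
  raw <- if (cosine) {
    as.numeric(unclass(pixels) %*% q) /
      (sqrt(rowSums(unclass(pixels)^2)) * sqrt(sum(q^2)))
  } else {
    as.numeric(unclass(pixels) %*% q) / length(q)
  }
  minmax_norm(raw)
}

#' Screen cube pixels by similarity to the leaf mean spectrum
#'
#' Extracts the leaf-mask pixels, Savitzky-Golay-smooths them (and the
#' reference spectrum), scores them with [pixel_similarity()] and keeps
#' either the top fraction `top_fraction` or all pixels with score at least
#' `threshold`. The surviving smoothed pixels form the unlabeled pool for
#' self-training. Deterministic: ties are broken by pixel raster order.
#'
#' @param cube An [hsi_cube()].
#' @param q Reference mean spectrum; defaults to the cube's leaf mean.
#' @param top_fraction Keep this fraction of highest-scoring pixels (in
#'   `(0, 1]`). Exactly one of `top_fraction`/`threshold` is used;
#'   `threshold` wins when both are given.
#' @param threshold Keep pixels with normalized score `>= threshold` (in
#'   `[0, 1]`).
#' @param window,polyorder Savitzky-Golay parameters.
#' @param cosine Passed to [pixel_similarity()].
#' @return A [spectrum_matrix()] of kept, smoothed pixel spectra with
#'   attribute `scores` (their normalized similarity scores).
#' @export
screen_pixels <- function(cube, q = NULL, top_fraction = 0.3,
                          threshold = NULL, window = 11L, polyorder = 2L,
                          cosine = FALSE) {
  stopifnot(inherits(cube, "hsi_cube"))
  if (is.null(q)) q <- mean_spectrum(cube, "leaf")
  px <- sg_smooth(cube_pixels(cube), window, polyorder)
  qs <- sg_smooth(q, window, polyorder)
  scores <- pixel_similarity(qs, px, cosine = cosine)
  keep <- if (!is.null(threshold)) {
    if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
    which(scores >= threshold)
  } else {
    if (top_fraction <= 0 || top_fraction > 1)
      stop("top_fraction must lie in (0, 1]")
    n_keep <- max(1L, floor(top_fraction * length(scores)))
    # stable order: ties broken by raster position
    order(-scores)[seq_len(n_keep)]
  }
  if (length(keep) == 0L)
    stop("screening rule keeps zero pixels: empty unlabeled pool")
  keep <- sort(keep)
  out <- px[keep, ]
  attr(out, "scores") <- scores[keep]
  out
}
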