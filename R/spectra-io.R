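#' Wavelength grids for the trimmed and raw band sets
#'
#' The spectrometer records 256 bands over 866--1701 nm; the first 32 bands
#' have a very low signal-to-noise ratio and are discarded, and the working
#' range of the retained 224 bands is 942--1680 nm. Both grids are exposed:
#' `default_wavelength_grid()` is the authoritative trimmed grid used by every
#' downstream type, `raw_wavelength_grid()` is the full instrument grid.
#'
#' @return Numeric vector of wavelengths in nm, strictly increasing.
#' @examples
#' g <- default_wavelength_grid()
#' length(g)        # 224
#' range(g)         # 942 1680
#' @export
default_wavelength_grid <- function() {
  seq(942, 1680, length.out = 224L)
}

#' @rdname default_wavelength_grid
#' @export
raw_wavelength_grid <- function() {
  seq(866, 1701, length.out = 256L)
}

#' Construct a spectrum matrix
#'
#' A `spectrum_matrix` is a numeric samples x bands reflectance matrix with
#' the wavelength grid (nm) attached as an attribute. It is the exchange type
#' used by every stage of the pipeline.
#'
#' @param values Numeric matrix, one row per sample, one column per band.
#' @param wavelengths Strictly increasing numeric vector, one entry per band.
#' @return A `spectrum_matrix` object.
#' @export
spectrum_matrix <- function(values, wavelengths) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("reflectance values must be numeric")
  if (length(wavelengths) != ncol(values))
    stop("wavelength vector length (", length(wavelengths),
         ") does not match band count (", ncol(values), ")")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (any(!is.finite(values)))
    stop("reflectance values contain NaN/Inf")
  structure(values, wavelengths = as.numeric(wavelengths),
            class = c("spectrum_matrix", "matrix", "array"))
}

#' @rdname spectrum_matrix
#' @param x Object to query.
#' @export
wavelengths <- function(x) attr(x, "wavelengths")

#' @export
print.spectrum_matrix <- function(x, ...) {
  wl <- wavelengths(x)
  cat(sprintf("spectrum_matrix: %d samples x %d bands (%.1f-%.1f nm)\n",
              nrow(x), ncol(x), min(wl), max(wl)))
  invisible(x)
}

# keep the wavelength grid when rows are subset; dropping columns must go
# through trim_bands() or explicit reconstruction
#' @export
`[.spectrum_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = FALSE)
  wl <- attr(x, "wavelengths")
  if (!missing(j)) wl <- wl[j]
  spectrum_matrix(out, wl)
}

#' Construct a hyperspectral leaf cube
#'
#' Holds an H x W x B reflectance array with its wavelength grid and two
#' pixel masks: `leaf_mask` (pixels on the leaf) and `vein_mask` (vein pixels,
#' a subset of the leaf mask).
#'
#' @param data Numeric H x W x B array.
#' @param wavelengths Strictly increasing numeric vector, length B.
#' @param leaf_mask,vein_mask Logical H x W matrices; `vein_mask` must be a
#'   subset of `leaf_mask`.
#' @return An `hsi_cube` object.
#' @export
hsi_cube <- function(data, wavelengths, leaf_mask, vein_mask) {
  if (length(dim(data)) != 3L) stop("cube data must be a 3-d array")
  d <- dim(data)
  if (length(wavelengths) != d[3])
    stop("wavelength vector length does not match band count")
  if (!identical(dim(leaf_mask), d[1:2]) || !identical(dim(vein_mask), d[1:2]))
    stop("mask dimensions do not match the cube")
  leaf_mask <- leaf_mask > 0; vein_mask <- vein_mask > 0
  if (any(vein_mask & !leaf_mask))
    stop("vein_mask must be a subset of leaf_mask")
  if (!any(leaf_mask)) stop("leaf_mask is empty: not a valid leaf")
  structure(list(data = data, wavelengths = as.numeric(wavelengths),
                 leaf_mask = leaf_mask, vein_mask = vein_mask),
            class = "hsi_cube")
}

#' @export
print.hsi_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("hsi_cube: %d x %d pixels, %d bands; %d leaf px (%d vein)\n",
              d[1], d[2], d[3], sum(x$leaf_mask), sum(x$vein_mask)))
  invisible(x)
}

#' Nutrient status classification scheme
#'
#' Five foliar status classes (VL, Low, Proper, High, VH) separated by four
#' concentration breakpoints in percent dry mass. The built-in schemes follow
#' the technical regulations for rubber foliar diagnosis: nitrogen breaks at
#' 2.90, 3.20, 3.40, 3.80 % and potassium at 0.70, 0.90, 1.10, 1.50 %.
#'
#' @param element "N" or "K", or pass `thresholds` directly for a custom
#'   scheme.
#' @param thresholds Four strictly increasing breakpoints (% dry mass).
#' @return A `class_scheme` object with fields `element`, `thresholds`,
#'   `class_names`.
#' @examples
#' classify_concentration(3.30, class_scheme("N"))  # 2 = Proper
#' @export
class_scheme <- function(element = c("N", "K"), thresholds = NULL) {
  element <- match.arg(element)
  if (is.null(thresholds))
    thresholds <- switch(element,
                         N = c(2.90, 3.20, 3.40, 3.80),
                         K = c(0.70, 0.90, 1.10, 1.50))
  if (length(thresholds) != 4L || any(diff(thresholds) <= 0))
    stop("thresholds must be 4 strictly increasing breakpoints")
  structure(list(element = element, thresholds = as.numeric(thresholds),
                 class_names = c("VL", "Low", "Proper", "High", "VH")),
            class = "class_scheme")
}

#' @rdname class_scheme
#' @param conc Numeric concentration vector (% dry mass).
#' @param scheme A `class_scheme`.
#' @return `classify_concentration` returns integer labels 0 (VL) to 4 (VH).
#'   A value equal to a breakpoint is assigned to the upper class.
#' @export
classify_concentration <- function(conc, scheme) {
  stopifnot(inherits(scheme, "class_scheme"))
  findInterval(conc, scheme$thresholds)
}

#' Construct a labeled spectral set
#'
#' Couples a `spectrum_matrix` with integer class labels 0--4 and optional
#' measured concentrations; the per-class counts are carried along.
#'
#' @param spectra A `spectrum_matrix`.
#' @param labels Integer labels in 0..4 (or class names resolvable through
#'   `scheme`), one per row of `spectra`.
#' @param concentrations Optional numeric vector of measured concentrations.
#' @param scheme Optional `class_scheme` used to resolve label names.
#' @return A `labeled_set` with fields `spectra`, `labels`, `concentrations`.
#' @export
labeled_set <- function(spectra, labels, concentrations = NULL,
                        scheme = class_scheme("N")) {
  stopifnot(inherits(spectra, "spectrum_matrix"))
  if (is.character(labels) || is.factor(labels)) {
    idx <- match(as.character(labels), scheme$class_names)
    if (anyNA(idx)) stop("unknown label token: ",
                         paste(unique(labels[is.na(idx)]), collapse = ", "))
    labels <- idx - 1L
  }
  labels <- as.integer(labels)
  if (length(labels) != nrow(spectra))
    stop("one label per spectrum required")
  if (any(labels < 0L | labels > 4L))
    stop("labels must lie in 0..4")
  if (!is.null(concentrations) && length(concentrations) != nrow(spectra))
    stop("one concentration per spectrum required")
  structure(list(spectra = spectra, labels = labels,
                 concentrations = concentrations),
            class = "labeled_set")
}

#' @rdname labeled_set
#' @param x A `labeled_set` (or an integer label vector).
#' @param n_classes Number of classes.
#' @return `class_counts` returns the per-class sample counts C_i.
#' @export
class_counts <- function(x, n_classes = 5L) {
  labels <- if (inherits(x, "labeled_set")) x$labels else as.integer(x)
  tabulate(labels + 1L, nbins = n_classes)
}

#' @export
print.labeled_set <- function(x, ...) {
  cat(sprintf("labeled_set: %d samples x %d bands; class counts %s\n",
              nrow(x$spectra), ncol(x$spectra),
              paste(class_counts(x), collapse = ":")))
  invisible(x)
}

#' Read and write labeled mean-spectrum tables
#'
#' CSV layout: 224 reflectance columns named `band_<wavelength>` (e.g.
#' `band_0942.0`), a `label` column (integer 0--4 or class name) and/or a
#' `concentration_pct` column. When only concentrations are present, labels
#' are derived through [classify_concentration()].
#'
#' @param path CSV file path.
#' @param scheme A [class_scheme()] used for label names and for deriving
#'   labels from concentrations.
#' @return A [labeled_set()].
#' @export
read_labeled_table <- function(path, scheme = class_scheme("N")) {
  df <- utils::read.csv(path, check.names = FALSE)
  band_cols <- grep("^band_", names(df), value = TRUE)
  if (length(band_cols) != 224L)
    stop("expected 224 band columns, found ", length(band_cols))
  wl <- as.numeric(sub("^band_", "", band_cols))
  spectra <- spectrum_matrix(as.matrix(df[band_cols]), wl)
  conc <- if ("concentration_pct" %in% names(df)) df$concentration_pct
  labels <- if ("label" %in% names(df)) {
    df$label
  } else if (!is.null(conc)) {
    classify_concentration(conc, scheme)
  } else stop("table has neither a 'label' nor a 'concentration_pct' column")
  labeled_set(spectra, labels, conc, scheme)
}

#' @rdname read_labeled_table
#' @param x A `labeled_set` to write.
#' @export
write_labeled_table <- function(x, path) {
  stopifnot(inherits(x, "labeled_set"))
  wl <- wavelengths(x$spectra)
  df <- as.data.frame(unclass(x$spectra)[, , drop = FALSE])
  names(df) <- sprintf("band_%06.1f", wl)
  df$label <- x$labels
  if (!is.null(x$concentrations)) df$concentration_pct <- x$concentrations
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Drop the leading low-signal bands
#'
#' Removes the first `n_drop` bands (default 32, taking a 256-band raw
#' spectrum to the 224 retained bands); the wavelength grid is trimmed in
#' lockstep. Works on both `spectrum_matrix` and `hsi_cube` inputs.
#'
#' @param x A `spectrum_matrix` or `hsi_cube`.
#' @param n_drop Number of leading bands to remove.
#' @return Object of the same type with `n_drop` fewer bands.
#' @export
trim_bands <- function(x, n_drop = 32L) UseMethod("trim_bands")

#' @export
trim_bands.spectrum_matrix <- function(x, n_drop = 32L) {
  n_drop <- as.integer(n_drop)
  if (n_drop < 0L) stop("n_drop must be non-negative")
  if (n_drop >= ncol(x)) stop("n_drop (", n_drop,
                              ") must be smaller than the band count")
  if (n_drop == 0L) return(x)
  keep <- (n_drop + 1L):ncol(x)
  spectrum_matrix(unclass(x)[, keep, drop = FALSE], wavelengths(x)[keep])
}

#' @export
trim_bands.hsi_cube <- function(x, n_drop = 32L) {
  n_drop <- as.integer(n_drop)
  if (n_drop < 0L) stop("n_drop must be non-negative")
  if (n_drop >= dim(x$data)[3]) stop("n_drop must be smaller than the band count")
  if (n_drop == 0L) return(x)
  keep <- (n_drop + 1L):dim(x$data)[3]
  hsi_cube(x$data[, , keep, drop = FALSE], x$wavelengths[keep],
           x$leaf_mask, x$vein_mask)
}

# ---- ENVI cube I/O -----------------------------------------------------
# Standard ENVI header (.hdr) + raw binary, float32, BIL/BIP/BSQ interleave.
# Masks travel as sidecar text matrices <stem>_leafmask.txt /
# <stem>_veinmask.txt (0/1, space-separated, H rows x W cols).

parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  get_num <- function(key) {
    m <- regmatches(txt, regexec(paste0(key, "\\s*=\\s*([0-9]+)"), txt))[[1]]
    if (length(m) < 2) stop("ENVI header missing '", key, "'")
    as.integer(m[2])
  }
  get_str <- function(key) {
    m <- regmatches(txt, regexec(paste0(key, "\\s*=\\s*(\\w+)"), txt))[[1]]
    if (length(m) < 2) stop("ENVI header missing '", key, "'")
    m[2]
  }
  wl_m <- regmatches(txt, regexec("wavelength\\s*=\\s*\\{([^}]*)\\}", txt))[[1]]
  if (length(wl_m) < 2) stop("ENVI header missing wavelength metadata")
  list(samples = get_num("samples"), lines = get_num("lines"),
       bands = get_num("bands"), interleave = tolower(get_str("interleave")),
       data_type = get_num("data type"),
       wavelengths = as.numeric(strsplit(wl_m[2], ",")[[1]]))
}

#' Read and write hyperspectral cubes in ENVI format
#'
#' Standard ENVI `.hdr` text header plus raw float32 binary, supporting all
#' three interleaves (BIL, BIP, BSQ). The in-memory layout is always
#' band-last (H x W x B) regardless of the on-disk interleave. Leaf and vein
#' masks are stored as 0/1 text matrices next to the raw file
#' (`<stem>_leafmask.txt`, `<stem>_veinmask.txt`).
#'
#' @param path Path to the `.hdr` header (or its stem).
#' @return `read_cube` returns an [hsi_cube()].
#' @export
read_cube <- function(path) {
  stem <- sub("\\.hdr$", "", path)
  hdr <- parse_envi_header(paste0(stem, ".hdr"))
  if (hdr$data_type != 4L) stop("only float32 (data type 4) cubes supported")
  H <- hdr$lines; W <- hdr$samples; B <- hdr$bands
  if (length(hdr$wavelengths) != B)
    stop("header declares ", B, " bands but lists ",
         length(hdr$wavelengths), " wavelengths")
  raw_path <- paste0(stem, ".dat")
  n <- file.size(raw_path) / 4
  if (!isTRUE(n == H * W * B))
    stop("raw file size does not match header dimensions (expected ",
         H * W * B, " float32 values, found ", n, ")")
  v <- readBin(raw_path, "numeric", n = H * W * B, size = 4, endian = "little")
  # readBin fills fastest-varying first; map each interleave's axis order
  # onto H x W x B via aperm
  data <- switch(hdr$interleave,
    bsq = aperm(array(v, dim = c(W, H, B)), c(2, 1, 3)),
    bil = aperm(array(v, dim = c(W, B, H)), c(3, 1, 2)),
    bip = aperm(array(v, dim = c(B, W, H)), c(3, 2, 1)),
    stop("unknown interleave '", hdr$interleave, "'"))
  read_mask <- function(suffix) {
    p <- paste0(stem, suffix)
    if (!file.exists(p)) return(matrix(TRUE, H, W))
    unname(as.matrix(utils::read.table(p))) > 0
  }
  hsi_cube(data, hdr$wavelengths, read_mask("_leafmask.txt"),
           read_mask("_veinmask.txt"))
}

#' @rdname read_cube
#' @param cube An [hsi_cube()] to write.
#' @param interleave On-disk interleave: "bil", "bip" or "bsq".
#' @export
write_cube <- function(cube, path, interleave = c("bil", "bip", "bsq")) {
  stopifnot(inherits(cube, "hsi_cube"))
  interleave <- match.arg(interleave)
  stem <- sub("\\.hdr$", "", path)
  d <- dim(cube$data); H <- d[1]; W <- d[2]; B <- d[3]
  hdr <- c("ENVI", "file type = ENVI Standard",
           paste0("samples = ", W), paste0("lines = ", H),
           paste0("bands = ", B), "data type = 4", "byte order = 0",
           paste0("interleave = ", interleave),
           paste0("wavelength = {",
                  paste(sprintf("%.12g", cube$wavelengths), collapse = ", "),
                  "}"))
  writeLines(hdr, paste0(stem, ".hdr"))
  v <- switch(interleave,
    bsq = as.vector(aperm(cube$data, c(2, 1, 3))),
    bil = as.vector(aperm(cube$data, c(2, 3, 1))),
    bip = as.vector(aperm(cube$data, c(3, 2, 1))))
  writeBin(as.numeric(v), paste0(stem, ".dat"), size = 4, endian = "little")
  utils::write.table(cube$leaf_mask * 1L, paste0(stem, "_leafmask.txt"),
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(cube$vein_mask * 1L, paste0(stem, "_veinmask.txt"),
                     row.names = FALSE, col.names = FALSE)
  invisible(stem)
}

#' Class counts of the study's data-division design
#'
#' Per-class sample counts (VL, Low, Proper, High, VH) of the train /
#' validation / test division used in the rubber-leaf study, for both
#' nutrients. These printed counts are inputs to the synthetic generator and
#' to imbalance arithmetic; the N division totals 1400 samples.
#'
#' @param element "N" or "K".
#' @return Named list of three integer 5-vectors: `train`, `validation`,
#'   `test`.
#' @export
split_design_counts <- function(element = c("N", "K")) {
  element <- match.arg(element)
  switch(element,
    N = list(train = c(45L, 93L, 225L, 104L, 268L),
             validation = c(19L, 43L, 83L, 49L, 121L),
             test = c(13L, 45L, 93L, 47L, 152L)),
    K = list(train = c(29L, 131L, 185L, 289L, 116L),
             validation = c(17L, 69L, 88L, 126L, 49L),
             test = c(16L, 75L, 87L, 128L, 44L)))
}
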