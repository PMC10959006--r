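test_that("wavelength grids span the documented ranges", {
  g <- default_wavelength_grid()
  expect_length(g, 224)
  expect_equal(g[1], 942)
  expect_equal(g[224], 1680)
  expect_equal(mean(diff(g)), 738 / 223, tolerance = 1e-12)
  r <- raw_wavelength_grid()
  expect_length(r, 256)
  expect_equal(range(r), c(866, 1701))
})

test_that("spectrum_matrix validates its invariants", {
  wl <- default_wavelength_grid()
  expect_error(spectrum_matrix(matrix(1, 2, 3), wl), "does not match")
  expect_error(spectrum_matrix(matrix(1, 2, 224), rev(wl)), "increasing")
  bad <- matrix(1, 2, 224); bad[1, 1] <- NaN
  expect_error(spectrum_matrix(bad, wl), "NaN")
  sm <- toy_matrix(3)
  expect_identical(wavelengths(sm), wl)
  sub <- sm[1:2, ]
  expect_s3_class(sub, "spectrum_matrix")
  expect_identical(wavelengths(sub), wl)
})

test_that("concentration thresholds map to the five status classes", {
  sN <- class_scheme("N")
  # interval 3.20-3.40 is Proper (class 2)
  expect_identical(classify_concentration(3.30, sN), 2L)
  expect_identical(classify_concentration(c(2.5, 3.0, 3.3, 3.6, 4.0), sN),
                   0:4)
  sK <- class_scheme("K")
  expect_identical(classify_concentration(c(0.5, 0.8, 1.0, 1.2, 2.0), sK),
                   0:4)
  # a breakpoint value belongs to the upper class
  expect_identical(classify_concentration(3.20, sN), 2L)
})

test_that("labeled tables round-trip through CSV", {
  p <- write_fixture_csv(labels = 0:4)
  ls1 <- read_labeled_table(p)
  expect_equal(class_counts(ls1), rep(1L, 5))
  p2 <- tempfile(fileext = ".csv")
  write_labeled_table(ls1, p2)
  ls2 <- read_labeled_table(p2)
  expect_equal(unclass(ls2$spectra), unclass(ls1$spectra),
               ignore_attr = TRUE)
  expect_identical(ls2$labels, ls1$labels)
})

test_that("labeled tables reject malformed input and derive labels", {
  expect_error(read_labeled_table(write_fixture_csv(labels = 0:4,
                                                    n_bands = 223)),
               "224 band columns")
  # concentrations only: labels derived from the scheme
  p <- write_fixture_csv(labels = NULL, conc = c(2.5, 3.30, 4.0))
  ls <- read_labeled_table(p, class_scheme("N"))
  expect_identical(ls$labels, c(0L, 2L, 4L))
  # named labels resolve through the scheme
  p2 <- write_fixture_csv(labels = c("VL", "Proper", "VH"))
  expect_identical(read_labeled_table(p2)$labels, c(0L, 2L, 4L))
  p3 <- write_fixture_csv(labels = c("VL", "bogus", "VH"))
  expect_error(read_labeled_table(p3), "unknown label")
})

test_that("band trimming drops leading bands in lockstep with wavelengths", {
  wl256 <- raw_wavelength_grid()
  m <- spectrum_matrix(matrix(runif(2 * 256), 2), wl256)
  tr <- trim_bands(m, 32)
  expect_equal(ncol(tr), 224)
  expect_identical(wavelengths(tr), wl256[33:256])
  expect_identical(unclass(tr), unclass(m)[, 33:256], ignore_attr = TRUE)
  expect_identical(trim_bands(m, 0), m)
  small <- spectrum_matrix(matrix(1:20 / 20, 2), 1:10)
  expect_error(trim_bands(small, 10), "smaller than the band count")
})

test_that("trimming a cube trims its wavelength grid too", {
  spec <- small_cube_spec()
  cube <- simulate_leaf_cube(spec, 12, 12, 2, 0.2, wl = raw_wavelength_grid())
  tr <- trim_bands(cube, 32)
  expect_equal(dim(tr$data)[3], 224)
  expect_equal(length(tr$wavelengths), 224)
  expect_identical(tr$leaf_mask, cube$leaf_mask)
})

test_that("ENVI cubes round-trip identically for every interleave", {
  spec <- small_cube_spec(seed = 11)
  cube <- simulate_leaf_cube(spec, 8, 9, 1, 0.25,
                             wl = default_wavelength_grid()[1:12])
  for (il in c("bil", "bip", "bsq")) {
    stem <- tempfile()
    write_cube(cube, stem, interleave = il)
    back <- read_cube(stem)
    # float32 on disk
    expect_equal(back$data, cube$data, tolerance = 1e-6)
    expect_identical(back$leaf_mask, cube$leaf_mask)
    expect_identical(back$vein_mask, cube$vein_mask)
    expect_equal(back$wavelengths, cube$wavelengths)
  }
})

test_that("ENVI de-interleave matches an explicit loop oracle", {
  spec <- small_cube_spec(seed = 13)
  cube <- simulate_leaf_cube(spec, 5, 6, 0, 0.3,
                             wl = default_wavelength_grid()[1:4])
  stem <- tempfile()
  write_cube(cube, stem, interleave = "bil")
  v <- readBin(paste0(stem, ".dat"), "numeric",
               n = prod(dim(cube$data)), size = 4, endian = "little")
  H <- 5; W <- 6; B <- 4
  oracle <- array(NA_real_, c(H, W, B))
  i <- 1
  for (line in 1:H) for (b in 1:B) for (s in 1:W) {
    oracle[line, s, b] <- v[i]; i <- i + 1
  }
  expect_equal(read_cube(stem)$data, oracle)
})

test_that("ENVI header/data size mismatches are rejected", {
  spec <- small_cube_spec(seed = 17)
  cube <- simulate_leaf_cube(spec, 5, 5, 2, 0.3,
                             wl = default_wavelength_grid()[1:6])
  stem <- tempfile()
  write_cube(cube, stem)
  hdr <- readLines(paste0(stem, ".hdr"))
  writeLines(sub("bands = 6", "bands = 8", hdr), paste0(stem, ".hdr"))
  expect_error(read_cube(stem), "wavelengths|size")
  writeLines(hdr[!grepl("wavelength", hdr)], paste0(stem, ".hdr"))
  expect_error(read_cube(stem), "wavelength")
})

test_that("hsi_cube enforces mask containment", {
  d <- array(0.5, c(3, 3, 2))
  leaf <- matrix(TRUE, 3, 3); vein <- matrix(FALSE, 3, 3)
  vein[1, 1] <- TRUE
  expect_s3_class(hsi_cube(d, 1:2, leaf, vein), "hsi_cube")
  leaf[1, 1] <- FALSE
  expect_error(hsi_cube(d, 1:2, leaf, vein), "subset")
  expect_error(hsi_cube(d, 1:2, matrix(FALSE, 3, 3), matrix(FALSE, 3, 3)),
               "empty")
})

test_that("the study's division counts are as printed", {
  n <- split_design_counts("N")
  expect_equal(n$train, c(45, 93, 225, 104, 268))
  k <- split_design_counts("K")
  expect_equal(k$train, c(29, 131, 185, 289, 116))
})
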