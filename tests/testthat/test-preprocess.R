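test_that("extract_peaks keeps strictly-above-threshold ions in order", {
  s <- msi_spectrum(c(100, 200, 300), c(5, 50, 500), 2, 3)
  expect_equal(extract_peaks(s, 50)$mz, 300)           # strict inequality
  expect_equal(extract_peaks(s, 0)$intensity, c(5, 50, 500))
  expect_equal(extract_peaks(s, 0)$x, rep(2L, 3))
  z <- msi_spectrum(c(1, 2), c(0, 1), 1, 1)
  expect_equal(extract_peaks(z, 0)$mz, 2)              # zero excluded at thr 0
  expect_error(extract_peaks(s, -1), "intensity_threshold")

  # brute-force count oracle on random spectra
  set.seed(41)
  for (rep in 1:5) {
    mzs <- sort(runif(200, 100, 1000))
    ints <- rexp(200, 1 / 50)
    thr <- runif(1, 0, 100)
    sp <- msi_spectrum(mzs, ints, 1, 1)
    expect_equal(nrow(extract_peaks(sp, thr)), sum(ints > thr))
  }
})

test_that("bin_ions groups by the ppm ladder", {
  near <- bin_ions(data.table::data.table(mz = c(400.0000, 400.0030),
                                          intensity = 1, x = 1L, y = 1L), 10)
  expect_equal(near$bin[1], near$bin[2])   # 3 mTh apart inside a 4 mTh window
  far <- bin_ions(data.table::data.table(mz = c(400.0000, 400.0100),
                                         intensity = 1, x = 1L, y = 1L), 10)
  expect_false(far$bin[1] == far$bin[2])
  expect_error(bin_ions(near, 0), "bin_ppm")
})

test_that("binning partitions random ions and bin widths respect the ppm bound", {
  set.seed(7)
  ions <- data.table::data.table(mz = runif(1000, 200, 1100),
                                 intensity = rexp(1000),
                                 x = sample(1:10, 1000, TRUE),
                                 y = sample(1:10, 1000, TRUE))
  binned <- bin_ions(ions, 10)
  # partition: multiset of m/z preserved, each ion exactly one bin
  expect_equal(sort(binned$mz), sort(ions$mz))
  expect_false(anyNA(binned$bin))
  # brute-force: every ion's bin index recomputed from the ladder definition
  m0 <- min(ions$mz)
  expect_equal(binned$bin,
               as.integer(floor((binned$mz / m0 - 1) / 1e-5 + 1e-12)))
  # within-bin spread is below the anchor-mass window
  spread <- binned[, .(d = max(mz) - min(mz), lo = min(mz)), by = bin]
  expect_true(all(spread$d <= 10e-6 * spread$lo + 1e-12))
})

test_that("define_features takes bin medians and counts detecting pixels", {
  ions <- data.table::data.table(
    mz = c(400.0000, 400.0010, 400.0020, 500.0000, 500.0030),
    intensity = 1,
    x = c(1L, 2L, 2L, 1L, 1L), y = 1L)
  feats <- define_features(bin_ions(ions, 10), n_spectra = 4)
  expect_equal(feats$mz, c(400.0010, 500.0015))        # odd and even medians
  expect_equal(feats$n_pixels, c(2L, 1L))
  expect_equal(feats$detection_fraction, c(0.5, 0.25)) # denominator = spectra
  expect_true(all(feats$bin_lo <= feats$mz & feats$mz <= feats$bin_hi))
  expect_true(all((feats$bin_hi - feats$bin_lo) / feats$mz <= 10e-6 * 2))
})

test_that("filter_features keeps strictly-above-threshold fractions", {
  f <- data.table::data.table(feature_id = 1:3, bin = 1:3, mz = c(400, 500, 600),
                              bin_lo = 0, bin_hi = 1000, n_ions = 1, n_pixels = 1,
                              detection_fraction = c(0.005, 0.02, 0.9))
  expect_equal(filter_features(f, 0.01)$mz, c(500, 600))
  expect_equal(nrow(filter_features(f, 0)), 3)         # all fractions > 0
  expect_error(filter_features(f, 1.2), "min_fraction")
  expect_error(filter_features(f, -0.1), "min_fraction")
})

test_that("build_feature_matrix sums within-bin ions and conserves intensity", {
  # pixel (1,1) carries two ions in one bin: entry must be their sum
  sp1 <- msi_spectrum(c(400.0000, 400.0020, 500.0), c(100, 50, 7), 1, 1)
  sp2 <- msi_spectrum(c(400.0010, 600.0), c(30, 9), 2, 1)
  ds <- msi_dataset(list(sp1, sp2))
  feats <- define_features(bin_ions(extract_all_ions <- lipidmsi:::extract_all_peaks(ds, 0), 10),
                           n_spectra = 2)
  mat <- build_feature_matrix(ds, feats, 0)
  i400 <- which(abs(mat$features$mz - 400.001) < 0.01)
  col1 <- which(mat$pixels$x == 1 & mat$pixels$y == 1)
  col2 <- which(mat$pixels$x == 2 & mat$pixels$y == 1)
  expect_equal(mat$intensities[i400, col1], 150)       # sum rule
  expect_equal(mat$intensities[i400, col2], 30)
  i600 <- which(abs(mat$features$mz - 600) < 0.01)
  expect_equal(mat$intensities[i600, col1], 0)         # absent ion -> 0
  # conservation: total above-threshold intensity equals matrix total
  expect_equal(sum(mat$intensities), sum(sp1$intensity, sp2$intensity))
})

test_that("matrix equals brute-force re-accumulation on a phantom", {
  ph <- generate_phantom(default_phantom_spec(10, 10, seed = 3))
  ds <- ph$dataset
  ions <- lipidmsi:::extract_all_peaks(ds, 0)
  feats <- filter_features(define_features(bin_ions(ions, 10), length(ds$spectra)), 0)
  mat <- build_feature_matrix(ds, feats, 0)
  # brute force: for every feature and pixel, linear scan of the raw spectra
  m0 <- attr(feats, "anchor_mz"); w <- attr(feats, "bin_ppm") * 1e-6
  for (i in sample(nrow(feats), 5)) {
    for (p in sample(nrow(mat$pixels), 5)) {
      s <- Filter(function(sp) sp$x == mat$pixels$x[p] && sp$y == mat$pixels$y[p],
                  ds$spectra)[[1]]
      in_bin <- floor((s$mz / m0 - 1) / w + 1e-12) == feats$bin[i]
      expect_equal(mat$intensities[i, p], sum(s$intensity[in_bin]))
    }
  }
  # total intensity conservation (min_fraction 0 keeps every bin)
  expect_equal(sum(mat$intensities), sum(ions$intensity))
})

test_that("raising thresholds never increases the feature count", {
  ph <- generate_phantom(default_phantom_spec(8, 8, seed = 9))
  ds <- ph$dataset
  n_feat <- function(thr, frac) {
    ions <- lipidmsi:::extract_all_peaks(ds, thr)
    nrow(filter_features(define_features(bin_ions(ions, 10), length(ds$spectra)), frac))
  }
  counts_thr <- vapply(c(0, 1, 5, 20, 60), n_feat, numeric(1), frac = 0)
  expect_true(all(diff(counts_thr) <= 0))
  counts_frac <- vapply(c(0, 0.05, 0.2, 0.5, 0.9), function(f) n_feat(0, f), numeric(1))
  expect_true(all(diff(counts_frac) <= 0))
})

test_that("mean_subset_spectrum is seed-deterministic and exact at the edges", {
  mat <- direct_matrix(matrix(c(1, 2, 3, 4, 5, 6), nrow = 2))
  expect_equal(mean_subset_spectrum(mat, 3, seed = 1), rowMeans(mat$intensities))
  one <- mean_subset_spectrum(mat, 1, seed = 5)
  expect_true(any(vapply(1:3, function(p)
    isTRUE(all.equal(one, mat$intensities[, p])), logical(1))))
  expect_identical(mean_subset_spectrum(mat, 2, seed = 11),
                   mean_subset_spectrum(mat, 2, seed = 11))
  expect_error(mean_subset_spectrum(mat, 0), "n_pixels")
  expect_error(mean_subset_spectrum(mat, 4), "n_pixels")
})
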