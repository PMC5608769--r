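test_that("estimate_carbons rounds the linear estimate and clamps at 1", {
  expect_equal(estimate_carbons(760.6), 42L)   # PC(34:1)+H neighbourhood, C42
  expect_equal(estimate_carbons(400.0), 22L)
  expect_equal(estimate_carbons(18.2), 1L)     # lower clamp
  expect_error(estimate_carbons(-5), "positive")
  expect_error(estimate_carbons(0), "positive")
})

test_that("expected ratios agree with the binomial pmf to 3 s.f.", {
  r1c <- expected_isotope_ratios(1)
  expect_equal(r1c$r1, 0.0111)
  expect_equal(r1c$r2, 0)                      # choose(1,2) = 0
  expect_equal(expected_isotope_ratios(100)$r1, 1.11)  # >1 is a valid ratio

  # oracle: exact binomial pmf P(k 13C | nC, p)/P(0); the linearised formula
  # must agree to ~nC*p relative accuracy (3 s.f. at nC = 42)
  for (nC in c(10, 42, 60)) {
    pm <- dbinom(0:2, nC, 0.0111)
    r <- expected_isotope_ratios(nC)
    expect_equal(r$r1, pm[2] / pm[1], tolerance = 0.02)
    expect_equal(r$r2, pm[3] / pm[1], tolerance = 0.03)
  }
  expect_equal(expected_isotope_ratios(42)$r1, 0.466, tolerance = 1e-3)
  expect_equal(expected_isotope_ratios(42)$r2, 0.1061, tolerance = 1e-3)
})

test_that("deisotope applies the acceptance band around the expected ratio", {
  # parent 760.585 (est. C42, r1 = 0.4662, band [0.2331, 0.6993] at tol 0.5)
  mk <- function(iso_mean) {
    direct_matrix(matrix(c(100, iso_mean), nrow = 2, ncol = 3),
                  mzs = c(760.585, 761.588))
  }
  hit <- deisotope(mk(45), c(100, 45))
  expect_equal(nrow(hit$matrix$intensities), 1)          # 0.45 inside band
  expect_equal(hit$matrix$features$mz, 760.585)
  expect_true(hit$report$accepted)

  miss <- deisotope(mk(95), c(100, 95))
  expect_equal(nrow(miss$matrix$intensities), 2)         # 0.95 outside band
  expect_false(miss$report$accepted)

  lone <- direct_matrix(matrix(c(100, 50), nrow = 2, ncol = 2),
                        mzs = c(760.585, 765.0))         # no M+1 in window
  none <- deisotope(lone, c(100, 50))
  expect_equal(nrow(none$matrix$intensities), 2)
  expect_equal(nrow(none$report), 0)

  expect_error(deisotope(mk(45), c(100, 45), ppm_window = 0), "ppm_window")
  expect_error(deisotope(mk(45), c(100, 45), tolerance = 0), "tolerance")
  expect_error(deisotope(mk(45), c(100, 45), tolerance = 1.5), "tolerance")
})

test_that("removed set matches the brute-force O(n^2) oracle on random instances", {
  set.seed(23)
  for (rep in 1:3) {
    n <- 500
    # random features with planted isotope pairs
    base <- sort(runif(n * 0.7, 300, 1000))
    parents <- sample(base, n * 0.15)
    iso <- parents + 1.003355 * sample(1:2, length(parents), TRUE)
    mzs <- sort(c(base, iso))
    means <- stats::setNames(rexp(length(mzs), 1 / 50) + 1, NULL)
    mat <- direct_matrix(matrix(rep(means, 3), ncol = 3), mzs = mzs)
    got <- deisotope(mat, means)
    removed_mz <- setdiff(mzs, got$matrix$features$mz)
    expect_equal(sort(removed_mz), sort(mzs[oracle_deisotope(mzs, means)]))
    # removed-set soundness: every removed feature has an accepted report row
    acc <- got$report[got$report$accepted]
    expect_setequal(removed_mz, unique(acc$isotope_mz))
    # every accepted isotope's parent survived
    expect_true(all(acc$parent_mz %in% got$matrix$features$mz))
  }
})

test_that("deisotoping is idempotent", {
  ph <- generate_phantom(default_phantom_spec(12, 12, seed = 2))
  ions <- lipidmsi:::extract_all_peaks(ph$dataset, 0)
  feats <- filter_features(define_features(bin_ions(ions, 10),
                                           length(ph$dataset$spectra)), 0.01)
  mat <- build_feature_matrix(ph$dataset, feats, 0)
  ms <- rowMeans(mat$intensities)
  d1 <- deisotope(mat, ms)
  d2 <- deisotope(d1$matrix, rowMeans(d1$matrix$intensities))
  expect_equal(d2$matrix$features$mz, d1$matrix$features$mz)
  expect_equal(d2$matrix$intensities, d1$matrix$intensities)
  expect_false(any(d2$report$accepted))
})

test_that("phantom M+1 recall >= 0.95 with zero monoisotopic false removals", {
  ph <- generate_phantom(default_phantom_spec(30, 30, seed = 6))
  ds <- ph$dataset
  ions <- lipidmsi:::extract_all_peaks(ds, 0)
  feats <- filter_features(define_features(bin_ions(ions, 10),
                                           length(ds$spectra)), 0.01)
  mat <- build_feature_matrix(ds, feats, 0)
  de <- deisotope(mat, mean_subset_spectrum(mat, min(500, ncol(mat$intensities)),
                                            seed = 1),
                  ppm_window = 10, tolerance = 0.5)
  surv <- de$matrix$features$mz
  m1 <- ph$species$mz + 1.003355
  recall <- mean(vapply(m1, function(m) !any(abs(surv - m) <= 10e-6 * m),
                        logical(1)))
  kept <- mean(vapply(ph$species$mz, function(m) any(abs(surv - m) <= 5e-6 * m),
                      logical(1)))
  expect_gte(recall, 0.95)
  expect_equal(kept, 1)
})
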