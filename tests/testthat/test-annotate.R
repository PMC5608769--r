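test_that("formula_mass matches the independent per-element oracle", {
  expect_equal(formula_mass("H2O"), 18.0105646, tolerance = 1e-6)
  expect_equal(formula_mass(c(C = 1)), 12)               # mass-scale anchor
  expect_equal(formula_mass("C42H82NO8P"), 759.57785, tolerance = 1e-4)
  for (f in c("C16H32O2", "C5H13NO3P", "C45H78O2", "C39H79N2O6P", "NaCl")) {
    expect_equal(formula_mass(f), oracle_mass(f), tolerance = 1e-10)
  }
  expect_error(formula_mass("C2Xe"), "unknown element")
  expect_error(formula_mass(character(0)))
  expect_error(formula_mass(c(C = 0)), "at least one atom")
})

test_that("build_species assembles known neutral formulas", {
  known <- list(
    list("PC", 34, 1, "C42H82NO8P"),
    list("PC", 36, 1, "C44H86NO8P"),
    list("FFA", 16, 0, "C16H32O2"),
    list("PE", 34, 1, "C39H76NO8P"),
    list("PS", 34, 1, "C40H76NO10P"),
    list("PA", 34, 1, "C37H71O8P"),
    list("PG", 34, 1, "C40H77O10P"),
    list("PI", 34, 1, "C43H81O13P"),
    list("DAG", 34, 1, "C37H70O5"),
    list("TAG", 52, 2, "C55H102O6"),
    list("CE", 18, 1, "C45H78O2"),
    list("Cer", 16, 0, "C34H67NO3"),    # N-acyl 16:0 on the d18:1 base
    list("SM", 16, 0, "C39H79N2O6P"),
    list("LysoPC", 16, 0, "C24H50NO7P"))
  for (k in known) {
    f <- build_species(k[[1]], k[[2]], k[[3]])
    expect_equal(lipidmsi:::format_formula(f), k[[4]])
    expect_equal(formula_mass(f), oracle_mass(k[[4]]), tolerance = 1e-10)
  }
  expect_error(build_species("PX", 34, 1), "unsupported")
  expect_error(build_species("PC", 34, 20), "infeasible")  # too many DBs
  expect_error(build_species("PC", 2, 0), "infeasible")    # below 2 C per chain
})

test_that("adduct_mz applies electron-corrected deltas", {
  expect_equal(adduct_mz(759.57785, "+H"), 760.58513, tolerance = 1e-4)
  # the white-matter marker ion [PC(36:1)+K]+
  pc361 <- formula_mass(build_species("PC", 36, 1))
  expect_equal(pc361, 787.60911, tolerance = 1e-4)
  expect_equal(adduct_mz(pc361, "+K"), 826.57227, tolerance = 1e-4)
  # additive inverse: -H then +H returns the neutral mass
  M <- 700.1234
  expect_equal(adduct_mz(adduct_mz(M, "-H"), "+H"), M, tolerance = 1e-9)
  expect_error(adduct_mz(-1, "+H"), "positive")
  expect_error(adduct_mz(700, "+Xy"), "unknown adduct")
})

test_that("every library m/z agrees with the ion-m/z oracle within 1e-4 Da", {
  for (mode in c("positive", "negative")) {
    lib <- build_library(mode)
    err <- vapply(seq_len(nrow(lib)), function(i) {
      abs(lib$mz[i] - oracle_ion_mz(lib$formula[i], lib$adduct[i]))
    }, numeric(1))
    expect_lt(max(err), 1e-4)
    expect_false(is.unsorted(lib$mz))
    expect_equal(anyDuplicated(lib[, c("class", "carbons", "double_bonds", "adduct")]), 0)
  }
})

test_that("library composition follows the per-mode class/adduct pairing", {
  pos <- build_library("positive")
  neg <- build_library("negative")
  expect_setequal(unique(pos$class),
                  c("DAG", "TAG", "PC", "PE", "PS", "LysoPC", "CE", "SM", "Cer"))
  expect_setequal(unique(pos$adduct), c("+H", "+Na", "+K", "+NH4"))
  expect_setequal(unique(neg$class), c("PC", "PA", "PE", "PS", "PG", "PI", "FFA"))
  expect_setequal(unique(neg$adduct), c("-H", "+Cl", "+OAc"))
  expect_error(build_library("negative", classes = character(0)), "empty class")
  expect_error(build_library("positive", adducts = "-H"), "not a positive-mode")

  # single-composition grid: 1 entry with the oracle m/z
  one <- build_library("positive", classes = "PC", adducts = "+H",
                       fa_grid = data.frame(c = 17, d = 0.5))
  expect_equal(nrow(one), 1)
  expect_equal(one$mz, 760.58513, tolerance = 1e-4)

  # entry count = |classes| x |compositions| x |adducts| for 1-chain classes
  grid <- data.frame(c = c(16, 18), d = 0)
  ffa <- build_library("negative", classes = "FFA", adducts = c("-H", "+Cl"),
                       fa_grid = grid)
  expect_equal(nrow(ffa), 2 * 2)

  # deterministic and order-independent of config listing order
  a <- build_library("positive", classes = c("PC", "Cer"), adducts = c("+K", "+H"))
  b <- build_library("positive", classes = c("Cer", "PC"), adducts = c("+H", "+K"))
  expect_identical(a, b)
})

test_that("annotate_features matches by signed ppm error", {
  lib <- build_library("positive", classes = "PC", adducts = "+H")
  hit <- annotate_features(data.frame(mz = 760.5851), lib, 5)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$name, "[PC(34:1)+H]+")
  expect_equal(hit$ppm_error, 1e6 * (760.5851 - hit$library_mz) / hit$library_mz)
  expect_lt(abs(hit$ppm_error), 1)
  miss <- annotate_features(data.frame(mz = 760.5900), lib, 5)
  expect_equal(nrow(miss), 0)                       # ~6.4 ppm away
  expect_equal(nrow(annotate_features(data.frame(mz = 760.5900), lib, 10)), 1)
  expect_error(annotate_features(data.frame(mz = 1), lib, 0), "ppm_tolerance")
})

test_that("annotation is complete vs brute force and monotone in tolerance", {
  lib <- build_library("positive")
  set.seed(17)
  feats <- data.frame(mz = sample(lib$mz, 60) * (1 + runif(60, -2e-5, 2e-5)))
  for (tol in c(3, 10)) {
    got <- annotate_features(feats, lib, tol)
    expect_true(all(abs(got$ppm_error) <= tol))     # soundness
    brute <- sum(vapply(feats$mz, function(m)
      sum(abs(1e6 * (m - lib$mz) / lib$mz) <= tol), numeric(1)))
    expect_equal(nrow(got), brute)                  # completeness
  }
  key <- function(a) paste(a$feature_mz, a$name)
  m3 <- annotate_features(feats, lib, 3)
  m10 <- annotate_features(feats, lib, 10)
  m50 <- annotate_features(feats, lib, 50)
  expect_true(all(key(m3) %in% key(m10)))
  expect_true(all(key(m10) %in% key(m50)))
})

test_that("difference_match finds configured mass deltas", {
  pair <- difference_match(data.frame(mz = c(700.5000, 716.4949)),
                           data.table::data.table(name = "oxidation(+O)",
                                                  delta = 15.994915), 5)
  expect_equal(nrow(pair), 1)
  expect_equal(pair$mz_a, 700.5)
  expect_equal(pair$delta_name, "oxidation(+O)")
  expect_error(difference_match(data.frame(mz = 1),
                                data.table::data.table()), "non-empty")

  # O(n^2) brute-force pair count on random features, all default deltas
  set.seed(29)
  mzs <- sort(runif(200, 300, 900))
  some <- sample(mzs, 30)
  mzs <- sort(c(mzs, some + 15.994915, some[1:10] + 37.955882))
  got <- difference_match(data.frame(mz = mzs), ppm_tolerance = 5)
  deltas <- default_difference_list()
  brute <- 0
  for (k in seq_len(nrow(deltas))) {
    for (i in seq_along(mzs)) for (j in seq_along(mzs)) {
      if (mzs[j] > mzs[i] &&
          abs(mzs[j] - mzs[i] - deltas$delta[k]) <= 5e-6 * mzs[j]) {
        brute <- brute + 1
      }
    }
  }
  expect_equal(nrow(got), brute)
  expect_gt(nrow(got), 0)
})
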