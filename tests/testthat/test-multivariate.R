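test_that("PCA recovers rank-1 structure and reconstructs the input", {
  set.seed(3)
  f1 <- rnorm(30)
  mat <- direct_matrix(rbind(f1, 2 * f1))          # f2 = 2*f1, noise-free
  sc <- center_pareto(mat)
  p <- msi_pca(sc, 2)
  expect_gte(p$explained_variance_fraction[1], 0.999)

  X <- t(sc$intensities)
  recon <- p$scores %*% t(p$loadings)
  expect_equal(recon, X, tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(msi_pca(sc, 5), "n_components")
})

test_that("PCA matches the covariance eigendecomposition oracle", {
  set.seed(19)
  X <- matrix(rnorm(100), 10, 10)                  # 10 pixels x 10 features
  mat <- lipidmsi:::new_msi_matrix(direct_matrix(t(X))$features, t(X),
                                   data.table::data.table(x = 1:10, y = 1L),
                                   scaled = TRUE)
  Xc <- sweep(X, 2, colMeans(X))
  matc <- lipidmsi:::new_msi_matrix(mat$features, t(Xc), mat$pixels, scaled = TRUE)
  p <- msi_pca(matc, 5)

  ev <- eigen(cov(Xc), symmetric = TRUE)           # oracle
  for (j in 1:5) {
    v <- ev$vectors[, j]
    if (v[which.max(abs(v))] < 0) v <- -v          # same sign convention
    expect_equal(p$loadings[, j], v, tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(p$scores[, j], Xc %*% v, tolerance = 1e-8, ignore_attr = TRUE)
  }
  expect_equal(p$explained_variance_fraction,
               (ev$values / sum(ev$values))[1:5], tolerance = 1e-8)
})

test_that("PCA loadings are orthonormal, variance fractions non-increasing, sign fixed", {
  set.seed(5)
  mat <- direct_matrix(matrix(rexp(150, 1 / 20), nrow = 10))
  p <- msi_pca(center_pareto(mat), 4)
  G <- t(p$loadings) %*% p$loadings
  expect_equal(G, diag(4), tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(p$explained_variance_fraction) <= 1e-12))
  expect_lte(sum(p$explained_variance_fraction), 1 + 1e-12)
  for (j in 1:4) expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  # deterministic across calls
  expect_identical(p$scores, msi_pca(center_pareto(mat), 4)$scores)
})

test_that("k-means separates well-separated groups and is seed-deterministic", {
  set.seed(8)
  X <- cbind(matrix(rnorm(40, 0, 0.1), 2), matrix(rnorm(40, 10, 0.1), 2))
  mat <- direct_matrix(X)
  km <- msi_kmeans(mat, k = 2, seed = 4)
  truth <- rep(1:2, each = 20)
  expect_equal(adjusted_rand_index(km$labels, truth), 1)
  expect_identical(km$labels, msi_kmeans(mat, k = 2, seed = 4)$labels)
  # objective non-increasing over iterations
  expect_true(all(diff(km$tot_withinss) <= 1e-9))

  one <- msi_kmeans(mat, k = 1, seed = 1)
  expect_equal(one$centers[1, ], rowMeans(X), ignore_attr = TRUE)
  expect_error(msi_kmeans(mat, k = 100, seed = 1), "k")
})

test_that("k-means objective decreases from deliberately poor seeds", {
  set.seed(44)
  X <- matrix(rnorm(300), nrow = 3)
  mat <- direct_matrix(X)
  for (seed in 1:5) {
    km <- msi_kmeans(mat, k = 4, seed = seed)
    expect_true(all(diff(km$tot_withinss) <= 1e-9))
    expect_equal(sort(unique(km$labels)), seq_len(4)[!km$empty])
  }
  kpp <- msi_kmeans(mat, k = 4, seed = 2, init = "kmeans++")
  expect_identical(kpp$labels, msi_kmeans(mat, k = 4, seed = 2, init = "kmeans++")$labels)
})

test_that("phantom regions are recovered with ARI >= 0.95", {
  ph <- generate_phantom(default_phantom_spec(30, 30, seed = 12))
  ions <- lipidmsi:::extract_all_peaks(ph$dataset, 0)
  feats <- filter_features(define_features(bin_ions(ions, 10),
                                           length(ph$dataset$spectra)), 0.01)
  mat <- build_feature_matrix(ph$dataset, feats, 0)
  norm <- normalise_matrix(mat, "TIC")
  km <- msi_kmeans(norm, k = 3, seed = 2)
  truth <- merge(cbind(km$pixels, lab = km$labels), ph$truth[ph$truth$region > 0],
                 by = c("x", "y"))
  expect_gte(adjusted_rand_index(truth$lab, truth$region), 0.95)
})

test_that("cluster_center_spectra equals the group-by-mean oracle", {
  set.seed(27)
  X <- matrix(rexp(100, 1 / 30), nrow = 5)         # 5 features x 20 pixels
  mat <- direct_matrix(X)
  km <- msi_kmeans(mat, k = 3, seed = 9)
  tab <- cluster_center_spectra(km, mat)
  for (j in 1:3) {
    members <- km$labels == j
    oracle <- if (any(members)) rowMeans(X[, members, drop = FALSE]) else rep(0, 5)
    expect_equal(tab[tab$cluster == j]$intensity, oracle, tolerance = 1e-8)
    expect_equal(unique(tab[tab$cluster == j]$empty), !any(members))
  }
  expect_equal(tab[tab$cluster == 1]$mz, mat$features$mz)

  one <- msi_kmeans(mat, k = 1, seed = 1)
  t1 <- cluster_center_spectra(one, mat)
  expect_equal(t1$intensity, rowMeans(X), tolerance = 1e-12)
})

test_that("adjusted_rand_index is permutation invariant and calibrated", {
  a <- rep(1:3, each = 10)
  expect_equal(adjusted_rand_index(a, a), 1)
  relab <- c(3, 1, 2)[a]
  expect_equal(adjusted_rand_index(a, relab), 1)
  set.seed(2)
  expect_lt(abs(adjusted_rand_index(a, sample(a))), 0.3)
})
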