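# Multivariate analysis of pixel spectra: PCA via singular value
# decomposition and k-means (Lloyd's algorithm) with deterministic seeded
# initialisation. Pixels are the observations and features the variables --
# the image-segmentation semantics, where clusters are tissue regions.

#' Principal components analysis of pixel spectra
#'
#' SVD of the pixels x features matrix (the transpose of the stored feature
#' matrix, which should already be centered and Pareto-scaled). Scores are
#' the pixel projections, loadings the right singular vectors. The sign of
#' each component is fixed so that its largest-magnitude loading element is
#' positive, making score images reproducible bit-for-bit.
#'
#' @param matrix a centered/scaled `msi_matrix` (see [center_pareto()]).
#' @param n_components number of components, at most `min(features, pixels)`.
#' @return object of class `msi_pca`: `scores` (pixels x k), `loadings`
#'   (features x k, orthonormal columns), `explained_variance_fraction`
#'   (non-increasing), `sdev`, `pixels`, `feature_mz`.
#' @export
msi_pca <- function(matrix, n_components = 5L) {
  stopifnot(inherits(matrix, "msi_matrix"))
  X <- t(matrix$intensities)  # pixels x features
  r <- min(dim(X))
  check_scalar_number(n_components, "n_components", lower = 1, upper = r)
  k <- as.integer(n_components)
  sv <- svd(X, nu = k, nv = k)
  for (j in seq_len(k)) {
    i_max <- which.max(abs(sv$v[, j]))
    if (sv$v[i_max, j] < 0) {
      sv$v[, j] <- -sv$v[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  scores <- sv$u %*% diag(sv$d[seq_len(k)], nrow = k)
  colnames(scores) <- colnames(sv$v) <- paste0("PC", seq_len(k))
  ev <- sv$d^2 / sum(sv$d^2)
  structure(list(scores = scores, loadings = sv$v,
                 explained_variance_fraction = ev[seq_len(k)],
                 sdev = sv$d[seq_len(k)] / sqrt(max(1, nrow(X) - 1)),
                 pixels = matrix$pixels, feature_mz = matrix$features$mz),
            class = "msi_pca")
}

#' @export
print.msi_pca <- function(x, ...) {
  cat(sprintf("<msi_pca> %d components; explained variance: %s\n",
              ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained_variance_fraction),
                    collapse = ", ")))
  invisible(x)
}

#' k-means clustering of pixels
#'
#' Lloyd's algorithm on pixel intensity vectors. Initial centers come from
#' seeded k-means++ seeding by default (`init = "sample"` draws `k` distinct
#' pixels uniformly instead); `n_start` restarts are run from seeds derived
#' deterministically from `seed` and the solution with the lowest final
#' within-cluster sum of squares is kept, so identical seeds always give
#' identical output. Each run iterates to convergence (maximum center shift
#' below `tol`) or `max_iter`; its total within-cluster sum of squares is
#' recorded per iteration and is non-increasing. Clusters that lose all
#' members keep their previous center and are flagged empty.
#'
#' @param matrix an `msi_matrix` (normalised intensities by default; pass a
#'   Pareto-scaled matrix to cluster on scaled data).
#' @param k number of clusters, `1 <= k <=` number of pixels. No default:
#'   the region count is tissue-specific.
#' @param seed integer seed for initialisation.
#' @param max_iter iteration cap per restart.
#' @param init `"kmeans++"` (default) or `"sample"` (k distinct pixels).
#' @param n_start number of seeded restarts; the best objective wins.
#' @param tol convergence threshold on the maximum center shift.
#' @return object of class `msi_kmeans`: `labels` (1..k per pixel),
#'   `centers` (k x features), `k`, `seed`, `iterations`, `tot_withinss`
#'   (per-iteration trace of the winning restart), `empty` (logical per
#'   cluster), `pixels`.
#' @export
msi_kmeans <- function(matrix, k, seed = 1L, max_iter = 100L,
                       init = c("kmeans++", "sample"), n_start = 5L,
                       tol = 1e-6) {
  stopifnot(inherits(matrix, "msi_matrix"))
  init <- match.arg(init)
  X <- t(matrix$intensities)  # pixels x features
  n <- nrow(X)
  check_scalar_number(k, "k", lower = 1, upper = n)
  check_scalar_number(n_start, "n_start", lower = 1)
  k <- as.integer(k)

  init_centers <- function(run_seed) withr_seed(run_seed, {
    if (init == "sample") {
      X[sample.int(n, k, replace = FALSE), , drop = FALSE]
    } else {
      idx <- sample.int(n, 1L)
      for (j in seq_len(k - 1L)) {
        d2 <- apply(X, 1, function(p) min(colSums((t(X[idx, , drop = FALSE]) - p)^2)))
        d2[idx] <- 0
        idx <- c(idx, if (sum(d2) > 0) sample.int(n, 1L, prob = d2) else
          sample(setdiff(seq_len(n), idx), 1L))
      }
      X[idx, , drop = FALSE]
    }
  })

  lloyd <- function(centers) {
    labels <- integer(n)
    trace <- numeric(0)
    iter <- 0L
    repeat {
      iter <- iter + 1L
      # squared distances pixels x centers
      d2 <- outer(rowSums(X^2), rep(1, k)) - 2 * X %*% t(centers) +
        outer(rep(1, n), rowSums(centers^2))
      labels <- max.col(-d2, ties.method = "first")
      trace <- c(trace, sum(d2[cbind(seq_len(n), labels)]))
      new_centers <- centers
      for (j in seq_len(k)) {
        members <- labels == j
        if (any(members)) new_centers[j, ] <- colMeans(X[members, , drop = FALSE])
      }
      shift <- max(sqrt(rowSums((new_centers - centers)^2)))
      centers <- new_centers
      if (shift < tol || iter >= max_iter) break
    }
    list(labels = labels, centers = centers, iterations = iter, trace = trace)
  }

  run_seeds <- withr_seed(seed, sample.int(.Machine$integer.max - 1L, n_start))
  best <- NULL
  for (rs in run_seeds) {
    fit <- lloyd(init_centers(rs))
    if (is.null(best) || utils::tail(fit$trace, 1) < utils::tail(best$trace, 1)) {
      best <- fit
    }
  }

  empty <- tabulate(best$labels, k) == 0L
  centers <- best$centers
  rownames(centers) <- paste0("cluster", seq_len(k))
  structure(list(labels = best$labels, centers = centers, k = k, seed = seed,
                 iterations = best$iterations, tot_withinss = best$trace,
                 empty = empty, pixels = matrix$pixels,
                 feature_mz = matrix$features$mz),
            class = "msi_kmeans")
}

#' @export
print.msi_kmeans <- function(x, ...) {
  cat(sprintf("<msi_kmeans> k = %d, %d iterations, within-SS %.4g\n",
              x$k, x$iterations, utils::tail(x$tot_withinss, 1)))
  invisible(x)
}

#' Cluster-center spectra table
#'
#' One row per (cluster, feature) with the cluster's mean intensity at that
#' feature: the "average spectrum" of each segmented region. Centers are
#' recomputed from the member pixel columns of `matrix`, so the table
#' reflects the matrix actually passed (e.g. normalised but unscaled
#' intensities even if clustering ran on scaled data). Empty clusters are
#' emitted with zero intensities and `empty = TRUE`.
#'
#' @param result an `msi_kmeans` result.
#' @param matrix the `msi_matrix` whose columns should be averaged.
#' @return data.table: `cluster`, `mz`, `intensity`, `n_pixels`, `empty`.
#' @export
cluster_center_spectra <- function(result, matrix) {
  stopifnot(inherits(result, "msi_kmeans"), inherits(matrix, "msi_matrix"))
  stopifnot(length(result$labels) == ncol(matrix$intensities))
  out <- list()
  for (j in seq_len(result$k)) {
    members <- result$labels == j
    center <- if (any(members)) {
      rowMeans(matrix$intensities[, members, drop = FALSE])
    } else rep(0, nrow(matrix$intensities))
    out[[j]] <- data.table::data.table(cluster = j, mz = matrix$features$mz,
                                       intensity = center,
                                       n_pixels = sum(members),
                                       empty = !any(members))
  }
  data.table::rbindlist(out)
}

#' Adjusted Rand Index between two pixel partitions
#'
#' Permutation-invariant agreement between two labelings (e.g. k-means
#' clusters vs ground-truth regions); 1 for identical partitions, ~0 for
#' independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return the ARI, a single number <= 1.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
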