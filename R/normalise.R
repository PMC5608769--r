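# Per-pixel intensity normalisation (median / TIC / standard ions) and
# centering + Pareto scaling of features ahead of multivariate analysis.

#' Normalise pixel intensity columns
#'
#' Each pixel column is divided by a per-pixel factor: the median of its
#' nonzero intensities (`"median"`), the sum of its intensities (`"TIC"`), or
#' the mean intensity of a set of standard-ion features (`"standards"`).
#' Columns whose factor is zero (empty pixels) are left all-zero and counted
#' in a warning. The median is taken over nonzero entries only: sparse MSI
#' columns are zero-dominated, and a median of zero would make the factor
#' degenerate.
#'
#' @param matrix an `msi_matrix`.
#' @param method `"TIC"`, `"median"`, `"standards"`, or `"none"`.
#' @param standard_mzs numeric m/z of the standard ions (required for
#'   `"standards"`); each must resolve to a feature within `ppm_tolerance`.
#' @param ppm_tolerance window for locating standard features.
#' @return the normalised `msi_matrix`.
#' @export
normalise_matrix <- function(matrix, method = c("TIC", "median", "standards", "none"),
                             standard_mzs = NULL, ppm_tolerance = 5) {
  stopifnot(inherits(matrix, "msi_matrix"))
  method <- match.arg(method)
  if (method == "none") return(matrix)
  X <- matrix$intensities
  if (method == "standards") {
    if (is.null(standard_mzs) || !length(standard_mzs)) {
      stop("method 'standards' requires standard_mzs", call. = FALSE)
    }
    rows <- integer(0)
    for (m in standard_mzs) {
      hit <- which(abs(matrix$features$mz - m) <= ppm_tolerance * 1e-6 * m)
      if (!length(hit)) {
        stop(sprintf("standard m/z %.5f does not resolve to any feature within %g ppm",
                     m, ppm_tolerance), call. = FALSE)
      }
      rows <- c(rows, hit)
    }
    f <- colMeans(X[unique(rows), , drop = FALSE])
  } else if (method == "TIC") {
    f <- colSums(X)
  } else {
    f <- apply(X, 2, function(col) {
      nz <- col[col > 0]
      if (length(nz)) stats::median(nz) else 0
    })
  }
  zero <- f == 0
  if (any(zero)) {
    warning(sprintf("%d pixel column(s) had a zero normalisation factor and were left as zero",
                    sum(zero)), call. = FALSE)
    f[zero] <- 1
  }
  out <- sweep(X, 2, f, "/")
  new_msi_matrix(matrix$features, out, matrix$pixels, scaled = matrix$scaled)
}

#' Center and Pareto-scale feature rows
#'
#' Per feature row, subtracts the across-pixel mean and divides by the square
#' root of the sample standard deviation (n - 1 denominator): Pareto scaling,
#' which damps the dominance of intense lipid features while retaining more
#' of the original variance structure than unit-variance scaling. Rows with
#' zero variance are set to all-zero (not dropped, to keep feature indexing
#' stable) and counted in a warning.
#'
#' @param matrix an `msi_matrix` with at least 2 pixels.
#' @return the scaled `msi_matrix` (`scaled = TRUE`; entries may be negative).
#' @export
center_pareto <- function(matrix) {
  stopifnot(inherits(matrix, "msi_matrix"))
  X <- matrix$intensities
  if (ncol(X) < 2L) stop("center_pareto requires at least 2 pixels", call. = FALSE)
  mu <- rowMeans(X)
  sd <- apply(X, 1, stats::sd)
  out <- X - mu
  degenerate <- sd == 0
  if (any(degenerate)) {
    warning(sprintf("%d zero-variance feature row(s) set to zero", sum(degenerate)),
            call. = FALSE)
    out[degenerate, ] <- 0
  }
  out[!degenerate, ] <- out[!degenerate, , drop = FALSE] / sqrt(sd[!degenerate])
  new_msi_matrix(matrix$features, out, matrix$pixels, scaled = TRUE)
}
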