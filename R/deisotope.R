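# Deisotoping: identify molecular ions (M) and strip their 13C isotope
# features at M+1.003355 and M+2.006710. The expected isotope intensity is
# predicted from an approximate carbon count estimated linearly from m/z
# (0.055 C/Da, the carbon density of glycerophospholipids), with the first two
# binomial 13C abundance terms at 1.11% per carbon.

C13_SPACING <- 1.003355   # 13C - 12C mass difference, Da
C13_ABUNDANCE <- 0.0111   # natural 13C isotopic abundance
C_PER_DA <- 0.055         # approx. carbons per Dalton for membrane lipids

#' Estimate the carbon count of a lipid ion from its m/z
#'
#' @param mz ion m/z (Th), > 0; vectorised.
#' @param c_per_da carbons per Dalton (default 0.055).
#' @return integer carbon count, at least 1.
#' @export
estimate_carbons <- function(mz, c_per_da = C_PER_DA) {
  if (!is.numeric(mz) || any(is.na(mz)) || any(mz <= 0)) {
    stop("mz must be positive", call. = FALSE)
  }
  pmax(1L, as.integer(round(c_per_da * mz)))
}

#' Expected M+1 and M+2 isotope intensity ratios
#'
#' Linearised binomial abundances for a molecule with `nC` carbons:
#' `r1 = nC * p` and `r2 = choose(nC, 2) * p^2` with `p = 0.0111`. These are
#' ratios relative to the monoisotopic intensity; `r1` may exceed 1 for very
#' large carbon counts, which is valid.
#'
#' @param nC integer carbon count >= 1; vectorised.
#' @param p13 per-carbon 13C abundance.
#' @return list with numeric vectors `r1`, `r2`.
#' @export
expected_isotope_ratios <- function(nC, p13 = C13_ABUNDANCE) {
  if (any(nC < 1)) stop("nC must be >= 1", call. = FALSE)
  list(r1 = nC * p13, r2 = choose(nC, 2) * p13^2)
}

#' Remove isotope features from a feature matrix
#'
#' Scans features in ascending m/z. Each feature not already claimed as an
#' isotope acts as a candidate parent M; any heavier feature within
#' `ppm_window` ppm of M+1.003355 (or M+2.006710) whose mean-intensity ratio
#' to M falls within `tolerance` of the expected ratio is flagged as an
#' isotope and its row removed. A feature removed as an isotope never serves
#' as a parent (the monoisotopic peak is always the lightest of its
#' envelope). M+1 and M+2 are tested independently of each other.
#'
#' Ratios are computed on the subset-mean spectrum, not per pixel, for
#' robustness to pixel noise.
#'
#' @param matrix an `msi_matrix`.
#' @param mean_spectrum per-feature mean intensities aligned to the matrix
#'   rows (see [mean_subset_spectrum()]); defaults to the full column mean.
#' @param ppm_window isotope m/z matching window, ppm of the parent (> 0).
#' @param tolerance relative half-width of the intensity acceptance band, in
#'   (0, 1]: observed/parent must lie in `[r*(1-tolerance), r*(1+tolerance)]`.
#' @param c_per_da,p13 constants for the expected-ratio model.
#' When two or more candidate features share one isotope window (a jittered
#' isotope peak population cut in two by a bin boundary) and their summed
#' intensity ratio fits the band, the group is treated as one split envelope
#' and removed together; such removals carry `via_group = TRUE` in the
#' report.
#'
#' @return list with `matrix` (rows of surviving features only) and `report`
#'   (data.table: `parent_mz`, `isotope_mz`, `order`, `observed_ratio`,
#'   `expected_ratio`, `accepted`, `via_group` for every tested candidate).
#' @export
deisotope <- function(matrix, mean_spectrum = NULL, ppm_window = 10,
                      tolerance = 0.5, c_per_da = C_PER_DA, p13 = C13_ABUNDANCE) {
  stopifnot(inherits(matrix, "msi_matrix"))
  check_scalar_number(ppm_window, "ppm_window", lower = 0, strict_lower = TRUE)
  check_scalar_number(tolerance, "tolerance", lower = 0, upper = 1,
                      strict_lower = TRUE)
  if (is.null(mean_spectrum)) mean_spectrum <- rowMeans(matrix$intensities)
  mzs <- matrix$features$mz
  stopifnot(length(mean_spectrum) == length(mzs))
  n <- length(mzs)
  removed <- logical(n)
  rep_rows <- vector("list", 0L)

  for (i in seq_len(n)) {
    if (removed[i] || mean_spectrum[i] <= 0) next
    nC <- estimate_carbons(mzs[i], c_per_da)
    exp_r <- expected_isotope_ratios(nC, p13)
    for (ord in 1:2) {
      target <- mzs[i] + ord * C13_SPACING
      tol <- ppm_window * 1e-6 * mzs[i]
      cand <- which(!removed & abs(mzs - target) <= tol & seq_len(n) > i)
      if (!length(cand)) next
      r_exp <- if (ord == 1L) exp_r$r1 else exp_r$r2
      in_band <- function(r) {
        r_exp > 0 && r >= r_exp * (1 - tolerance) && r <= r_exp * (1 + tolerance)
      }
      obs <- mean_spectrum[cand] / mean_spectrum[i]
      ok <- vapply(obs, in_band, logical(1))
      # Split-envelope rescue: ppm-ladder bin boundaries can cut one jittered
      # isotope peak population into adjacent features, each carrying only
      # part of the envelope intensity. When several candidates share the
      # window and their summed ratio fits the band, the whole group is one
      # isotope envelope and is removed together.
      via_group <- rep(FALSE, length(cand))
      if (length(cand) > 1L && !all(ok) && in_band(sum(obs))) {
        via_group <- !ok
        ok[] <- TRUE
      }
      for (ci in seq_along(cand)) {
        rep_rows[[length(rep_rows) + 1L]] <- data.table::data.table(
          parent_mz = mzs[i], isotope_mz = mzs[cand[ci]], order = ord,
          observed_ratio = obs[ci], expected_ratio = r_exp,
          accepted = ok[ci], via_group = via_group[ci])
        if (ok[ci]) removed[cand[ci]] <- TRUE
      }
    }
  }

  report <- if (length(rep_rows)) data.table::rbindlist(rep_rows) else
    data.table::data.table(parent_mz = numeric(), isotope_mz = numeric(),
                           order = integer(), observed_ratio = numeric(),
                           expected_ratio = numeric(), accepted = logical(),
                           via_group = logical())
  keep <- which(!removed)
  feats <- matrix$features[keep, ]
  feats[, feature_id := seq_len(.N)]
  data.table::setattr(feats, "anchor_mz", attr(matrix$features, "anchor_mz"))
  data.table::setattr(feats, "bin_ppm", attr(matrix$features, "bin_ppm"))
  out <- new_msi_matrix(feats, matrix$intensities[keep, , drop = FALSE],
                        matrix$pixels, scaled = matrix$scaled)
  list(matrix = out, report = report)
}
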