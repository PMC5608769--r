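# Pre-processing: threshold extraction, ppm-ladder mass binning, feature
# definition by bin median m/z, detection-proportion filtering, and assembly
# of the feature x pixel intensity matrix.

#' Extract above-threshold ions from a spectrum
#'
#' @param spectrum an [msi_spectrum()].
#' @param intensity_threshold keep ions with intensity strictly greater than
#'   this (default 0: all non-zero centroids).
#' @return data.table with columns `mz`, `intensity`, `x`, `y`, in the
#'   spectrum's original (ascending m/z) order.
#' @export
extract_peaks <- function(spectrum, intensity_threshold = 0) {
  stopifnot(inherits(spectrum, "msi_spectrum"))
  check_scalar_number(intensity_threshold, "intensity_threshold", lower = 0)
  keep <- spectrum$intensity > intensity_threshold
  data.table::data.table(mz = spectrum$mz[keep],
                         intensity = spectrum$intensity[keep],
                         x = spectrum$x, y = spectrum$y)
}

# All above-threshold ions of a dataset, one row per ion.
extract_all_peaks <- function(dataset, intensity_threshold = 0) {
  stopifnot(inherits(dataset, "msi_dataset"))
  check_scalar_number(intensity_threshold, "intensity_threshold", lower = 0)
  if (!length(dataset$spectra)) {
    return(data.table::data.table(mz = numeric(), intensity = numeric(),
                                  x = integer(), y = integer()))
  }
  data.table::rbindlist(lapply(dataset$spectra, extract_peaks,
                               intensity_threshold = intensity_threshold))
}

#' Group ions into ppm-width mass bins
#'
#' Bins form a fixed ladder anchored at the smallest ion m/z `m0`: bin `k`
#' spans `[m0 * (1 + k*w), m0 * (1 + (k+1)*w))` with `w = bin_ppm * 1e-6`.
#' The ladder is deterministic and independent of ion order, and every ion
#' falls in exactly one bin. At the anchor mass the bin width equals `bin_ppm`
#' ppm; at higher masses it is slightly narrower in relative terms, which only
#' makes the grouping more conservative.
#'
#' @param ions data.table with at least an `mz` column (as from
#'   [extract_peaks()]); sorted internally if needed.
#' @param bin_ppm bin width in parts per million of the anchor mass (> 0).
#' @return the ion table with an integer `bin` column added, sorted by m/z,
#'   with attributes `anchor_mz` and `bin_ppm`.
#' @export
bin_ions <- function(ions, bin_ppm = 10) {
  check_scalar_number(bin_ppm, "bin_ppm", lower = 0, strict_lower = TRUE)
  ions <- data.table::as.data.table(ions)
  if (!"mz" %in% names(ions)) stop("ions must have an mz column", call. = FALSE)
  ions <- ions[order(mz)]
  w <- bin_ppm * 1e-6
  if (nrow(ions)) {
    m0 <- ions$mz[1L]
    ions[, bin := as.integer(floor((mz / m0 - 1) / w + 1e-12))]
  } else {
    m0 <- NA_real_
    ions[, bin := integer()]
  }
  data.table::setattr(ions, "anchor_mz", m0)
  data.table::setattr(ions, "bin_ppm", bin_ppm)
  ions[]
}

#' Define spectral features from mass bins
#'
#' Each occupied bin becomes one feature whose m/z is the median of its member
#' ion m/z values. The detection fraction is the number of distinct pixels
#' contributing at least one member ion, divided by the number of acquired
#' spectra (not the grid size: off-tissue missing pixels do not dilute
#' detection).
#'
#' @param bins binned ion table from [bin_ions()].
#' @param n_spectra number of acquired spectra in the dataset.
#' @return data.table of class `msi_features` with columns `feature_id`,
#'   `bin`, `mz`, `bin_lo`, `bin_hi`, `n_ions`, `n_pixels`,
#'   `detection_fraction`, sorted by `mz`; carries the binning attributes.
#' @export
define_features <- function(bins, n_spectra) {
  stopifnot(data.table::is.data.table(bins), "bin" %in% names(bins))
  check_scalar_number(n_spectra, "n_spectra", lower = 1)
  m0 <- attr(bins, "anchor_mz")
  w <- attr(bins, "bin_ppm") * 1e-6
  feats <- bins[, .(mz = stats::median(mz), n_ions = .N,
                    n_pixels = data.table::uniqueN(paste(x, y))),
                by = bin]
  feats[, `:=`(bin_lo = m0 * (1 + bin * w),
               bin_hi = m0 * (1 + (bin + 1) * w),
               detection_fraction = n_pixels / n_spectra)]
  data.table::setorder(feats, mz)
  feats[, feature_id := seq_len(.N)]
  data.table::setcolorder(feats, c("feature_id", "bin", "mz", "bin_lo", "bin_hi",
                                   "n_ions", "n_pixels", "detection_fraction"))
  data.table::setattr(feats, "anchor_mz", m0)
  data.table::setattr(feats, "bin_ppm", attr(bins, "bin_ppm"))
  data.table::setattr(feats, "class", c("msi_features", class(feats)))
  feats[]
}

#' Filter features by detection proportion
#'
#' Keeps exactly the features detected in strictly more than `min_fraction`
#' of acquired spectra, preserving order.
#'
#' @param features an `msi_features` table from [define_features()].
#' @param min_fraction detection-proportion threshold in `[0, 1]`.
#' @return the retained subset, same class and attributes.
#' @export
filter_features <- function(features, min_fraction = 0.01) {
  stopifnot("detection_fraction" %in% names(features))
  check_scalar_number(min_fraction, "min_fraction", lower = 0, upper = 1)
  out <- features[features$detection_fraction > min_fraction, ]
  data.table::setattr(out, "anchor_mz", attr(features, "anchor_mz"))
  data.table::setattr(out, "bin_ppm", attr(features, "bin_ppm"))
  out
}

# Fixed raster order of acquired pixels: y-major (row by row), then x.
raster_pixels <- function(dataset) {
  px <- data.table::data.table(
    x = vapply(dataset$spectra, `[[`, integer(1), "x"),
    y = vapply(dataset$spectra, `[[`, integer(1), "y"))
  data.table::setorder(px, y, x)
  px
}

#' Build the feature x pixel intensity matrix
#'
#' Entry (i, p) is the sum of the intensities of pixel p's above-threshold
#' ions that fall in feature i's bin, or 0 if none. Summing (rather than
#' taking the maximum) conserves the total ion count later used for TIC
#' normalisation. Ions in bins that were filtered out contribute to no
#' feature. Pixel columns follow a fixed raster order (by y, then x).
#'
#' @param dataset the [msi_dataset()].
#' @param features filtered `msi_features`.
#' @param intensity_threshold same threshold used for extraction.
#' @return an `msi_matrix` (features, intensity matrix, pixel index).
#' @export
build_feature_matrix <- function(dataset, features, intensity_threshold = 0) {
  stopifnot(inherits(dataset, "msi_dataset"))
  px <- raster_pixels(dataset)
  px[, col := seq_len(.N)]
  ions <- extract_all_peaks(dataset, intensity_threshold)
  m0 <- attr(features, "anchor_mz")
  w <- attr(features, "bin_ppm") * 1e-6
  mat <- matrix(0, nrow = nrow(features), ncol = nrow(px))
  if (nrow(ions)) {
    ions[, bin := as.integer(floor((mz / m0 - 1) / w + 1e-12))]
    row_of <- stats::setNames(seq_len(nrow(features)), as.character(features$bin))
    ions[, row := row_of[as.character(bin)]]
    ions <- merge(ions, px, by = c("x", "y"), sort = FALSE)
    ions <- ions[!is.na(row)]
    if (nrow(ions)) {
      acc <- ions[, .(value = sum(intensity)), by = .(row, col)]
      mat[cbind(acc$row, acc$col)] <- acc$value
    }
  }
  new_msi_matrix(features, mat, px[, .(x, y)])
}

#' Mean spectrum over a random subset of pixels
#'
#' Per-feature arithmetic mean over a seed-reproducible uniform sample of
#' `n_pixels` distinct pixels, used downstream for deisotoping.
#'
#' @param matrix an `msi_matrix`.
#' @param n_pixels subset size, between 1 and the number of pixels.
#' @param seed integer seed; identical seeds give identical subsets.
#' @return numeric vector, one mean intensity per feature.
#' @export
mean_subset_spectrum <- function(matrix, n_pixels = ncol(matrix$intensities),
                                 seed = 1L) {
  stopifnot(inherits(matrix, "msi_matrix"))
  np <- ncol(matrix$intensities)
  check_scalar_number(n_pixels, "n_pixels", lower = 1, upper = np)
  cols <- withr_seed(seed, sample.int(np, n_pixels, replace = FALSE))
  rowMeans(matrix$intensities[, cols, drop = FALSE])
}

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Export the feature table as CSV
#'
#' @param features an `msi_features` table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  data.table::fwrite(features[, .(mz, bin_lo, bin_hi, detection_fraction)], path)
  invisible(path)
}
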