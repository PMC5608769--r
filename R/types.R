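#' Construct a single-pixel mass spectrum
#'
#' A spectrum is a centroided peak list (m/z, intensity) attached to one pixel
#' of the imaging raster. m/z values must be strictly increasing and
#' intensities non-negative; pixel coordinates are 1-based, following the imzML
#' convention.
#'
#' @param mz numeric vector of m/z values (Th), strictly increasing.
#' @param intensity numeric vector of ion intensities, same length as `mz`.
#' @param x,y integer pixel coordinates, both >= 1.
#' @return An object of class `msi_spectrum` with fields `mz`, `intensity`,
#'   `x`, `y`.
#' @examples
#' s <- msi_spectrum(c(400.1, 500.2), c(10, 20), x = 1, y = 1)
#' @export
msi_spectrum <- function(mz, intensity, x, y) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity)) {
    stop("mz and intensity must have equal length", call. = FALSE)
  }
  if (length(mz) > 1L && any(diff(mz) <= 0)) {
    stop("mz must be strictly increasing", call. = FALSE)
  }
  if (any(intensity < 0)) stop("intensities must be non-negative", call. = FALSE)
  x <- as.integer(x); y <- as.integer(y)
  if (length(x) != 1L || length(y) != 1L || is.na(x) || is.na(y) || x < 1L || y < 1L) {
    stop("pixel coordinates must be single integers >= 1", call. = FALSE)
  }
  structure(list(mz = mz, intensity = intensity, x = x, y = y),
            class = "msi_spectrum")
}

#' Construct an MSI dataset
#'
#' A dataset is a collection of per-pixel spectra on an integer pixel grid.
#' Missing pixels (sparse grids, off-tissue positions) are simply absent from
#' `spectra`; downstream they behave as all-zero and render as background.
#'
#' @param spectra list of [msi_spectrum()] objects, at most one per (x, y).
#' @param polarity `"positive"`, `"negative"`, or `NA` if unknown.
#' @param source_path optional path the data was read from.
#' @return An object of class `msi_dataset` with fields `spectra`,
#'   `grid` (named `c(n_x, n_y)` extents), `polarity`, `source_path`.
#' @export
msi_dataset <- function(spectra, polarity = NA_character_, source_path = NA_character_) {
  stopifnot(is.list(spectra))
  for (s in spectra) {
    if (!inherits(s, "msi_spectrum")) stop("all elements must be msi_spectrum", call. = FALSE)
  }
  if (length(spectra)) {
    xs <- vapply(spectra, `[[`, integer(1), "x")
    ys <- vapply(spectra, `[[`, integer(1), "y")
    if (anyDuplicated(paste(xs, ys))) {
      stop("at most one spectrum per pixel (x, y)", call. = FALSE)
    }
    grid <- c(n_x = max(xs), n_y = max(ys))
  } else {
    grid <- c(n_x = 0L, n_y = 0L)
  }
  if (!is.na(polarity)) polarity <- match.arg(polarity, c("positive", "negative"))
  structure(list(spectra = spectra, grid = grid, polarity = polarity,
                 source_path = source_path),
            class = "msi_dataset")
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat(sprintf("<msi_dataset> %d spectra on a %d x %d grid, polarity: %s\n",
              length(x$spectra), x$grid[["n_x"]], x$grid[["n_y"]],
              ifelse(is.na(x$polarity), "unset", x$polarity)))
  invisible(x)
}

#' @export
print.msi_spectrum <- function(x, ...) {
  cat(sprintf("<msi_spectrum> pixel (%d, %d), %d peaks\n", x$x, x$y, length(x$mz)))
  invisible(x)
}

# Internal constructor for the feature x pixel matrix container. `features` is
# a data.table (feature_id, mz, bin_lo, bin_hi, detection_fraction, ...),
# `intensities` an n_features x n_pixels numeric matrix, `pixels` a data.table
# (x, y) in fixed raster order (y-major). `scaled` marks matrices that have
# been centered/scaled and may hold negative entries.
new_msi_matrix <- function(features, intensities, pixels, scaled = FALSE) {
  structure(list(features = features, intensities = intensities,
                 pixels = pixels, scaled = scaled),
            class = "msi_matrix")
}

#' @export
print.msi_matrix <- function(x, ...) {
  cat(sprintf("<msi_matrix> %d features x %d pixels%s\n",
              nrow(x$intensities), ncol(x$intensities),
              if (isTRUE(x$scaled)) " (centered/scaled)" else ""))
  invisible(x)
}

#' @export
dim.msi_matrix <- function(x) dim(x$intensities)

# shared validation helpers
check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                               strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("%s must be a single number", name), call. = FALSE)
  }
  if (strict_lower) {
    if (x <= lower) stop(sprintf("%s must be > %s", name, lower), call. = FALSE)
  } else if (x < lower) {
    stop(sprintf("%s must be >= %s", name, lower), call. = FALSE)
  }
  if (x > upper) stop(sprintf("%s must be <= %s", name, upper), call. = FALSE)
  invisible(x)
}
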