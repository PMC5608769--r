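# Image "slicing" and rendering: one value per acquired pixel is placed on
# the 2-D acquisition grid (ion intensity maps, PCA score maps, cluster-label
# maps). Orientation contract: increasing y runs down the image, increasing x
# runs right. Pixels without spectra carry NA (never 0 -- zero is a valid
# intensity) and render as background.

#' Slice a per-pixel value vector into a 2-D image
#'
#' @param values one value per acquired pixel, aligned with `pixel_index`.
#' @param grid named `c(n_x, n_y)` grid extents.
#' @param pixel_index data.frame/data.table of (x, y) for the acquired
#'   pixels, in the same order as `values`.
#' @param value_kind `"intensity"`, `"score"`, or `"label"`.
#' @param mz optional m/z (or component/cluster id) the image depicts.
#' @return object of class `msi_image`: `grid` (n_y x n_x matrix, NA at
#'   missing pixels), `value_kind`, `mz`.
#' @export
slice_image <- function(values, grid, pixel_index,
                        value_kind = c("intensity", "score", "label"),
                        mz = NA_real_) {
  value_kind <- match.arg(value_kind)
  stopifnot(length(values) == nrow(pixel_index))
  n_x <- grid[["n_x"]]; n_y <- grid[["n_y"]]
  if (any(pixel_index$x < 1L | pixel_index$x > n_x |
          pixel_index$y < 1L | pixel_index$y > n_y)) {
    stop("pixel coordinates fall outside the grid", call. = FALSE)
  }
  img <- matrix(NA_real_, nrow = n_y, ncol = n_x)
  img[cbind(pixel_index$y, pixel_index$x)] <- values
  structure(list(grid = img, value_kind = value_kind, mz = mz),
            class = "msi_image")
}

#' @export
print.msi_image <- function(x, ...) {
  cat(sprintf("<msi_image> %d x %d %s image\n",
              ncol(x$grid), nrow(x$grid), x$value_kind))
  invisible(x)
}

# Map image values to hex colors. Intensity/score images use a continuous
# palette with the maximum at the palette top (linear) or after an arcsinh
# transform; label images use a categorical palette. NA -> background.
image_colors <- function(image, colormap = NULL, scale = c("linear", "arcsinh"),
                         background = "#000000", n_levels = 256L) {
  scale <- match.arg(scale)
  v <- image$grid
  if (image$value_kind == "label") {
    labs <- sort(unique(stats::na.omit(as.vector(v))))
    pal <- if (is.null(colormap)) grDevices::hcl.colors(max(3L, length(labs)), "Dark 3")
           else colormap
    col <- matrix(background, nrow = nrow(v), ncol = ncol(v))
    for (i in seq_along(labs)) col[!is.na(v) & v == labs[i]] <- pal[i]
    return(col)
  }
  if (scale == "arcsinh") v <- asinh(v)
  pal <- if (is.null(colormap)) grDevices::hcl.colors(n_levels, "viridis")
         else grDevices::colorRampPalette(colormap)(n_levels)
  rng <- range(v, na.rm = TRUE)
  idx <- if (diff(rng) == 0) {
    matrix(n_levels, nrow = nrow(v), ncol = ncol(v))
  } else {
    1L + floor((v - rng[1]) / diff(rng) * (n_levels - 1L) + 1e-9)
  }
  col <- matrix(background, nrow = nrow(v), ncol = ncol(v))
  col[!is.na(v)] <- pal[idx[!is.na(v)]]
  col
}

write_ppm <- function(col_matrix, path) {
  rgb <- grDevices::col2rgb(t(col_matrix))  # 3 x (n_x * n_y), row-major
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", sprintf("%d %d", ncol(col_matrix), nrow(col_matrix)), "255"), con)
  writeLines(paste(as.vector(rgb), collapse = " "), con)
  invisible(path)
}

#' Render an image to a raster file
#'
#' Writes PNG (via the R graphics device) or plain-text portable pixmap
#' (PPM, "P3"), chosen by the file extension. PPM output is byte-level
#' deterministic and trivially machine-readable; PNG is the presentation
#' format. Row 1 of the image is the top of the raster (y increases
#' downwards), missing pixels render as the background color.
#'
#' @param image an `msi_image`.
#' @param path output path ending in `.png` or `.ppm`.
#' @param colormap `NULL` for the defaults (perceptually uniform viridis for
#'   continuous values, a categorical palette for labels), or a vector of
#'   colors.
#' @param scale `"linear"` or `"arcsinh"` value transform (continuous images).
#' @param background color for missing pixels.
#' @param pixel_size magnification factor for PNG output.
#' @return `path`, invisibly.
#' @export
render_image <- function(image, path, colormap = NULL,
                         scale = c("linear", "arcsinh"),
                         background = "#000000", pixel_size = 8L) {
  stopifnot(inherits(image, "msi_image"))
  col <- image_colors(image, colormap, scale, background)
  ext <- tolower(tools::file_ext(path))
  if (ext == "ppm") {
    write_ppm(col, path)
  } else if (ext == "png") {
    grDevices::png(path, width = ncol(col) * pixel_size,
                   height = nrow(col) * pixel_size)
    op <- graphics::par(mar = c(0, 0, 0, 0))
    on.exit({ graphics::par(op); grDevices::dev.off() })
    graphics::plot.new()
    graphics::rasterImage(grDevices::as.raster(col), 0, 0, 1, 1, interpolate = FALSE)
  } else {
    stop(sprintf("unsupported image format: .%s (use .png or .ppm)", ext),
         call. = FALSE)
  }
  invisible(path)
}

#' Overlay up to three ion images as RGB channels
#'
#' Mirrors the common red/green/blue composite of marker lipids: each image
#' is scaled to its own maximum and mapped to one channel.
#'
#' @param images list of 1--3 `msi_image` objects on the same grid.
#' @param path output `.png` or `.ppm` path.
#' @return `path`, invisibly.
#' @export
render_overlay <- function(images, path) {
  stopifnot(length(images) >= 1L, length(images) <= 3L)
  dims <- dim(images[[1]]$grid)
  chan <- vector("list", 3)
  for (i in 1:3) {
    if (i <= length(images)) {
      v <- images[[i]]$grid
      stopifnot(identical(dim(v), dims))
      mx <- max(v, na.rm = TRUE)
      v <- if (mx > 0) v / mx else v
      v[is.na(v)] <- 0
      chan[[i]] <- pmin(pmax(v, 0), 1)
    } else {
      chan[[i]] <- matrix(0, dims[1], dims[2])
    }
  }
  col <- matrix(grDevices::rgb(chan[[1]], chan[[2]], chan[[3]]), dims[1], dims[2])
  ext <- tolower(tools::file_ext(path))
  if (ext == "ppm") write_ppm(col, path)
  else {
    img <- structure(list(grid = matrix(1, dims[1], dims[2]),
                          value_kind = "intensity", mz = NA_real_),
                     class = "msi_image")
    grDevices::png(path, width = dims[2] * 8L, height = dims[1] * 8L)
    op <- graphics::par(mar = c(0, 0, 0, 0))
    on.exit({ graphics::par(op); grDevices::dev.off() })
    graphics::plot.new()
    graphics::rasterImage(grDevices::as.raster(col), 0, 0, 1, 1, interpolate = FALSE)
  }
  invisible(path)
}

#' Export an image grid as CSV
#'
#' @param image an `msi_image`.
#' @param path output CSV path (n_y rows, n_x columns, empty cells for
#'   missing pixels).
#' @return `path`, invisibly.
#' @export
write_image_csv <- function(image, path) {
  utils::write.table(image$grid, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, na = "")
  invisible(path)
}
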