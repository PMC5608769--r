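# Full pipeline runner: read -> threshold/bin/define/filter -> matrix ->
# deisotope -> annotate (+ difference match) -> normalise -> scale ->
# PCA + k-means -> images, with every artifact written to an output
# directory together with the effective configuration and a run log.

#' Assemble a pipeline configuration
#'
#' Every stage parameter in one validated list; unset values take the
#' documented defaults. The effective configuration is written to the output
#' directory by [run_pipeline()], so a run is reproducible from its artifacts.
#'
#' @param bin_ppm mass-bin width, ppm (default 10: suited to ~60,000
#'   resolving power; widen for lower-resolution instruments).
#' @param intensity_threshold keep ions with intensity strictly above this.
#' @param min_fraction detection-proportion filter in `[0, 1]`.
#' @param subset_n pixels averaged for the deisotoping mean spectrum
#'   (`NULL`: `min(500, n_pixels)`).
#' @param deisotope_ppm,deisotope_tolerance isotope matching window (ppm) and
#'   relative intensity acceptance half-width.
#' @param skip_deisotope bypass isotope removal.
#' @param polarity `"positive"`/`"negative"`; `NULL` to take it from the
#'   imzML metadata.
#' @param classes,adducts,fa_grid library composition overrides (see
#'   [build_library()]).
#' @param ppm_tolerance annotation match window, ppm.
#' @param deltas mass-difference table for [difference_match()].
#' @param normalisation `"TIC"`, `"median"`, `"standards"`, or `"none"`.
#' @param standard_mzs standard-ion m/z list (required when
#'   `normalisation = "standards"`).
#' @param n_components PCA components to report.
#' @param k number of k-means clusters; no default -- the expected region
#'   count is tissue-specific and must be chosen by the analyst.
#' @param kmeans_scaled cluster on Pareto-scaled (rather than normalised)
#'   intensities.
#' @param n_ion_images how many single-ion images to render (most intense
#'   features first), or a numeric vector of feature m/z to image.
#' @param image_format `"png"` or `"ppm"`.
#' @param seed master seed for subsetting and clustering.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(bin_ppm = 10, intensity_threshold = 0,
                            min_fraction = 0.01, subset_n = NULL,
                            deisotope_ppm = 10, deisotope_tolerance = 0.5,
                            skip_deisotope = FALSE, polarity = NULL,
                            classes = NULL, adducts = NULL,
                            fa_grid = default_fa_grid(),
                            ppm_tolerance = 5,
                            deltas = default_difference_list(),
                            normalisation = "TIC", standard_mzs = NULL,
                            n_components = 5L, k = NULL,
                            kmeans_scaled = FALSE, n_ion_images = 3L,
                            image_format = "png", seed = 1L) {
  check_scalar_number(bin_ppm, "bin_ppm", lower = 0, strict_lower = TRUE)
  check_scalar_number(intensity_threshold, "intensity_threshold", lower = 0)
  check_scalar_number(min_fraction, "min_fraction", lower = 0, upper = 1)
  check_scalar_number(deisotope_ppm, "deisotope_ppm", lower = 0, strict_lower = TRUE)
  check_scalar_number(deisotope_tolerance, "deisotope_tolerance", lower = 0,
                      upper = 1, strict_lower = TRUE)
  check_scalar_number(ppm_tolerance, "ppm_tolerance", lower = 0, strict_lower = TRUE)
  check_scalar_number(n_components, "n_components", lower = 1)
  if (!is.null(k)) check_scalar_number(k, "k", lower = 1)
  normalisation <- match.arg(normalisation, c("TIC", "median", "standards", "none"))
  if (normalisation == "standards" && !length(standard_mzs)) {
    stop("normalisation 'standards' requires standard_mzs", call. = FALSE)
  }
  if (!is.null(polarity)) polarity <- match.arg(polarity, c("positive", "negative"))
  image_format <- match.arg(image_format, c("png", "ppm"))
  structure(list(bin_ppm = bin_ppm, intensity_threshold = intensity_threshold,
                 min_fraction = min_fraction, subset_n = subset_n,
                 deisotope_ppm = deisotope_ppm,
                 deisotope_tolerance = deisotope_tolerance,
                 skip_deisotope = isTRUE(skip_deisotope), polarity = polarity,
                 classes = classes, adducts = adducts, fa_grid = fa_grid,
                 ppm_tolerance = ppm_tolerance, deltas = deltas,
                 normalisation = normalisation, standard_mzs = standard_mzs,
                 n_components = as.integer(n_components),
                 k = if (is.null(k)) NULL else as.integer(k),
                 kmeans_scaled = isTRUE(kmeans_scaled),
                 n_ion_images = n_ion_images, image_format = image_format,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

config_lines <- function(config) {
  fmt <- function(v) {
    if (is.null(v)) "NULL"
    else if (is.data.frame(v)) paste0("<table:", nrow(v), " rows>")
    else paste(format(v, scientific = FALSE, trim = TRUE), collapse = ",")
  }
  paste0(names(config), " = ", vapply(config, fmt, character(1)))
}

#' Run the full processing pipeline
#'
#' Executes every stage on one imzML file (or an in-memory dataset) and
#' writes all artifacts to `out_dir`: the effective configuration, feature
#' table, isotope report, lipid library, annotations, difference pairs,
#' cluster centers and labels, PCA loadings/scores/variance, single-ion and
#' score and cluster images, and a run log. A stage failure writes a FAILED
#' marker naming the stage and rethrows; artifacts from completed stages are
#' retained.
#'
#' @param config a [pipeline_config()]; `config$k` must be set.
#' @param input path to a `.imzML` file (ignored when `dataset` is given).
#' @param out_dir output directory, created if needed.
#' @param dataset optional in-memory [msi_dataset()] instead of `input`.
#' @return invisibly, a list with the principal in-memory results
#'   (`matrix`, `deisotoped`, `annotations`, `pca`, `clusters`, ...).
#' @export
run_pipeline <- function(config, input = NULL, out_dir, dataset = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$k)) {
    stop("config$k (number of clusters) must be set for a full pipeline run",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  img_dir <- file.path(out_dir, "images")
  dir.create(img_dir, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  log_msg <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    sprintf(...))
    writeLines(line, log_con)
    message(line)
  }
  stage <- "setup"
  fail <- function(e) {
    writeLines(sprintf("stage: %s\nerror: %s", stage, conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }

  res <- list()
  tryCatch({
    writeLines(config_lines(unclass(config)), file.path(out_dir, "config_effective.txt"))

    stage <- "read"
    if (is.null(dataset)) {
      log_msg("reading %s", input)
      dataset <- read_imzml(input)
    }
    log_msg("dataset: %d spectra on %d x %d grid", length(dataset$spectra),
            dataset$grid[["n_x"]], dataset$grid[["n_y"]])
    polarity <- if (!is.null(config$polarity)) config$polarity else dataset$polarity
    if (is.na(polarity)) {
      stop("polarity not present in file metadata; set config$polarity")
    }

    stage <- "features"
    ions <- extract_all_peaks(dataset, config$intensity_threshold)
    bins <- bin_ions(ions, config$bin_ppm)
    features <- define_features(bins, n_spectra = length(dataset$spectra))
    features <- filter_features(features, config$min_fraction)
    log_msg("%d ions -> %d features after %g%% detection filter", nrow(ions),
            nrow(features), 100 * config$min_fraction)

    stage <- "matrix"
    mat <- build_feature_matrix(dataset, features, config$intensity_threshold)
    write_feature_table(features, file.path(out_dir, "feature_table.csv"))

    stage <- "deisotope"
    if (config$skip_deisotope) {
      log_msg("deisotoping skipped")
      deiso <- list(matrix = mat, report = NULL)
    } else {
      subset_n <- if (is.null(config$subset_n)) {
        min(500L, ncol(mat$intensities))
      } else min(config$subset_n, ncol(mat$intensities))
      mean_spec <- mean_subset_spectrum(mat, subset_n, seed = config$seed)
      deiso <- deisotope(mat, mean_spec, ppm_window = config$deisotope_ppm,
                         tolerance = config$deisotope_tolerance)
      data.table::fwrite(deiso$report, file.path(out_dir, "isotope_report.csv"))
      log_msg("deisotoping removed %d of %d features",
              nrow(mat$intensities) - nrow(deiso$matrix$intensities),
              nrow(mat$intensities))
    }
    dmat <- deiso$matrix

    stage <- "annotate"
    lib <- build_library(polarity, classes = config$classes,
                         adducts = config$adducts, fa_grid = config$fa_grid)
    data.table::fwrite(lib, file.path(out_dir, "library.csv"))
    ann <- annotate_features(dmat$features, lib, config$ppm_tolerance)
    data.table::fwrite(ann, file.path(out_dir, "annotations.csv"))
    diffs <- difference_match(dmat$features, config$deltas, config$ppm_tolerance)
    data.table::fwrite(diffs, file.path(out_dir, "difference_pairs.csv"))
    log_msg("%d annotations at %g ppm; %d difference pairs", nrow(ann),
            config$ppm_tolerance, nrow(diffs))

    stage <- "normalise"
    norm <- normalise_matrix(dmat, config$normalisation,
                             standard_mzs = config$standard_mzs,
                             ppm_tolerance = config$ppm_tolerance)

    stage <- "scale"
    scaled <- center_pareto(norm)

    stage <- "pca"
    ncomp <- min(config$n_components, nrow(scaled$intensities),
                 ncol(scaled$intensities))
    pca <- msi_pca(scaled, ncomp)
    data.table::fwrite(
      data.table::data.table(mz = pca$feature_mz, pca$loadings),
      file.path(out_dir, "pca_loadings.csv"))
    data.table::fwrite(
      data.table::data.table(pca$pixels, pca$scores),
      file.path(out_dir, "pca_scores.csv"))
    data.table::fwrite(
      data.table::data.table(component = seq_len(ncomp),
                             explained_variance_fraction = pca$explained_variance_fraction),
      file.path(out_dir, "pca_variance.csv"))

    stage <- "cluster"
    km <- msi_kmeans(if (config$kmeans_scaled) scaled else norm,
                     k = config$k, seed = config$seed)
    centers <- cluster_center_spectra(km, norm)
    data.table::fwrite(centers, file.path(out_dir, "cluster_centers.csv"))
    data.table::fwrite(
      data.table::data.table(km$pixels, cluster = km$labels),
      file.path(out_dir, "cluster_labels.csv"))
    log_msg("k-means: k = %d, %d iterations", km$k, km$iterations)

    stage <- "images"
    ext <- config$image_format
    ion_mzs <- if (is.numeric(config$n_ion_images) && length(config$n_ion_images) > 1) {
      config$n_ion_images
    } else {
      means <- rowMeans(norm$intensities)
      norm$features$mz[order(-means)][seq_len(min(config$n_ion_images,
                                                  nrow(norm$features)))]
    }
    for (m in ion_mzs) {
      i <- which.min(abs(norm$features$mz - m))
      img <- slice_image(norm$intensities[i, ], dataset$grid, norm$pixels,
                         value_kind = "intensity", mz = norm$features$mz[i])
      render_image(img, file.path(img_dir, sprintf("ion_%.4f.%s",
                                                   norm$features$mz[i], ext)))
    }
    for (j in seq_len(ncomp)) {
      img <- slice_image(pca$scores[, j], dataset$grid, pca$pixels,
                         value_kind = "score", mz = j)
      render_image(img, file.path(img_dir, sprintf("score_PC%d.%s", j, ext)))
    }
    cl_img <- slice_image(km$labels, dataset$grid, km$pixels,
                          value_kind = "label")
    render_image(cl_img, file.path(img_dir, sprintf("clusters.%s", ext)))
    log_msg("done")

    res <- list(dataset = dataset, features = features, matrix = mat,
                deisotoped = dmat, isotope_report = deiso$report,
                library = lib, annotations = ann, differences = diffs,
                normalised = norm, scaled = scaled, pca = pca, clusters = km,
                cluster_centers = centers, out_dir = out_dir)
  }, error = fail)
  invisible(res)
}

# ---- feature-matrix CSV round-trip (staged CLI runs) -----------------------

#' Write a feature matrix (with its feature table) to CSV
#'
#' Columns: `mz`, `bin_lo`, `bin_hi`, `detection_fraction`, then one
#' `px_<x>_<y>` intensity column per pixel in raster order. The binning
#' attributes travel in a `# anchor_mz=...; bin_ppm=...` header comment.
#'
#' @param matrix an `msi_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(matrix, path) {
  stopifnot(inherits(matrix, "msi_matrix"))
  hdr <- sprintf("# anchor_mz=%.12g; bin_ppm=%.12g",
                 attr(matrix$features, "anchor_mz"),
                 attr(matrix$features, "bin_ppm"))
  # %.17g: doubles survive the decimal round-trip exactly, so staged runs on
  # this CSV reproduce in-memory results bit-for-bit
  c17 <- function(v) sprintf("%.17g", v)
  dt <- data.table::data.table(matrix$features[, .(bin, mz = c17(mz),
                                                   bin_lo = c17(bin_lo),
                                                   bin_hi = c17(bin_hi),
                                                   detection_fraction = c17(detection_fraction))])
  px_names <- sprintf("px_%d_%d", matrix$pixels$x, matrix$pixels$y)
  inten <- data.table::as.data.table(
    matrix(c17(matrix$intensities), nrow = nrow(matrix$intensities)))
  data.table::setnames(inten, px_names)
  writeLines(hdr, path)
  data.table::fwrite(cbind(dt, inten), path, append = TRUE, col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_matrix_csv()]
#'
#' @param path CSV path.
#' @return an `msi_matrix`.
#' @export
read_matrix_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  anchor <- as.numeric(sub(".*anchor_mz=([^;]+);.*", "\\1", hdr))
  ppm <- as.numeric(sub(".*bin_ppm=([^;]+).*", "\\1", hdr))
  dt <- data.table::fread(path, skip = 1L)
  px_cols <- grep("^px_", names(dt), value = TRUE)
  feats <- dt[, .(bin, mz, bin_lo, bin_hi, detection_fraction)]
  feats[, feature_id := seq_len(.N)]
  data.table::setcolorder(feats, c("feature_id", "bin"))
  data.table::setattr(feats, "anchor_mz", anchor)
  data.table::setattr(feats, "bin_ppm", ppm)
  data.table::setattr(feats, "class", c("msi_features", class(feats)))
  xy <- do.call(rbind, strsplit(sub("^px_", "", px_cols), "_"))
  pixels <- data.table::data.table(x = as.integer(xy[, 1]),
                                   y = as.integer(xy[, 2]))
  new_msi_matrix(feats, as.matrix(dt[, px_cols, with = FALSE]), pixels)
}
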