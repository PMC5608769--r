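# Synthetic MSI phantom generator. Emulates a MALDI lipid imaging experiment
# on a rectangular pixel grid: a few tissue regions, each expressing a
# distinct panel of lipid species observed as adduct ions with
# natural-abundance 13C isotope peaks, multiplicative log-normal intensity
# noise, and empty off-tissue pixels. Output is standard imzML plus a ground
# truth table, so every pipeline stage can be validated without external
# data.

#' Specify a synthetic MSI phantom
#'
#' @param grid named `c(n_x, n_y)` raster extents.
#' @param regions list of regions; each a list with `mask` (an n_y x n_x
#'   logical matrix, `TRUE` where the region lies; masks must be disjoint)
#'   and `panel` (data.frame with columns `class`, `carbons`, `double_bonds`,
#'   `adduct`, `intensity` -- one lipid adduct ion per row, base intensity
#'   > 0).
#' @param mode ionisation mode of the simulated acquisition.
#' @param isotope_orders subset of `0:2`: which envelope peaks to emit
#'   (0 = monoisotopic).
#' @param noise_cv coefficient of variation of the multiplicative log-normal
#'   intensity noise (0 = noise-free).
#' @param dropout_fraction fraction of in-tissue pixels randomly dropped
#'   (simulating failed acquisitions), in `[0, 1)`.
#' @param isotope_jitter_ppm half-width of the uniform m/z jitter applied to
#'   isotope peaks (exercises the binning tolerance).
#' @param seed integer seed; generation is fully deterministic given the spec.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid, regions, mode = "positive", isotope_orders = 0:2,
                         noise_cv = 0.2, dropout_fraction = 0.05,
                         isotope_jitter_ppm = 1, seed = 1L) {
  stopifnot(all(c("n_x", "n_y") %in% names(grid)), length(regions) >= 1L)
  check_scalar_number(noise_cv, "noise_cv", lower = 0)
  check_scalar_number(dropout_fraction, "dropout_fraction", lower = 0, upper = 1 - 1e-12)
  stopifnot(all(isotope_orders %in% 0:2), 0 %in% isotope_orders)
  cover <- matrix(0L, grid[["n_y"]], grid[["n_x"]])
  for (r in regions) {
    stopifnot(is.matrix(r$mask),
              nrow(r$mask) == grid[["n_y"]], ncol(r$mask) == grid[["n_x"]])
    stopifnot(all(c("class", "carbons", "double_bonds", "adduct", "intensity")
                  %in% names(r$panel)))
    if (any(r$panel$intensity <= 0)) stop("base intensities must be > 0", call. = FALSE)
    cover <- cover + r$mask
  }
  if (any(cover > 1L)) stop("region masks must be disjoint", call. = FALSE)
  structure(list(grid = grid, regions = regions, mode = mode,
                 isotope_orders = sort(unique(isotope_orders)),
                 noise_cv = noise_cv, dropout_fraction = dropout_fraction,
                 isotope_jitter_ppm = isotope_jitter_ppm, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Exact binomial 13C envelope ratios relative to the monoisotopic peak for a
# molecule with nC carbons: P(k)/P(0) = choose(nC, k) * (p/(1-p))^k.
binomial_isotope_ratios <- function(nC, p13 = C13_ABUNDANCE) {
  q <- p13 / (1 - p13)
  c(r1 = nC * q, r2 = choose(nC, 2) * q^2)
}

#' Default three-region phantom specification
#'
#' A cerebellum-like stated world: a rectangular tissue slab containing three
#' horizontal-band regions on a 2-pixel off-tissue border, each region
#' expressing four lipid adduct ions (twelve species in total) spanning PC,
#' PE, PS, SM, Cer, DAG, TAG, LysoPC and CE with K+/H+/Na+/NH4+ adducts.
#' Noise and dropout defaults: 20% multiplicative CV, 5% in-tissue dropout,
#' full M/M+1/M+2 envelopes with 1 ppm isotope jitter.
#'
#' @param n_x,n_y grid extents.
#' @param seed integer seed.
#' @return a [phantom_spec()].
#' @export
default_phantom_spec <- function(n_x = 50L, n_y = 50L, seed = 1L) {
  border <- 2L
  band <- function(rows) {
    m <- matrix(FALSE, n_y, n_x)
    m[rows, (border + 1L):(n_x - border)] <- TRUE
    m
  }
  tissue_rows <- (border + 1L):(n_y - border)
  cuts <- round(stats::quantile(tissue_rows, c(1 / 3, 2 / 3)))
  panel <- function(classes, carbons, dbs, adducts, base) {
    data.frame(class = classes, carbons = carbons, double_bonds = dbs,
               adduct = adducts, intensity = base, stringsAsFactors = FALSE)
  }
  regions <- list(
    # white-matter-like: saturated PC-rich panel
    list(mask = band(tissue_rows[tissue_rows <= cuts[1]]),
         panel = panel(c("PC", "PC", "PE", "SM"),
                       c(36L, 34L, 38L, 18L), c(1L, 1L, 4L, 0L),
                       c("+K", "+H", "+H", "+H"),
                       c(150, 120, 90, 80))),
    # granular-layer-like
    list(mask = band(tissue_rows[tissue_rows > cuts[1] & tissue_rows <= cuts[2]]),
         panel = panel(c("PC", "PS", "DAG", "Cer"),
                       c(38L, 36L, 36L, 24L), c(6L, 1L, 2L, 1L),
                       c("+K", "+H", "+Na", "+H"),
                       c(140, 100, 85, 70))),
    # molecular-layer-like
    list(mask = band(tissue_rows[tissue_rows > cuts[2]]),
         panel = panel(c("PC", "TAG", "LysoPC", "CE"),
                       c(40L, 52L, 16L, 18L), c(6L, 2L, 0L, 1L),
                       c("+K", "+NH4", "+H", "+Na"),
                       c(130, 95, 75, 60))))
  phantom_spec(grid = c(n_x = n_x, n_y = n_y), regions = regions, seed = seed)
}

#' Generate a synthetic MSI dataset from a phantom specification
#'
#' Each in-tissue pixel receives one peak per panel species at the species'
#' library m/z, with intensity `base * LN(1, noise_cv)` (log-normal with unit
#' mean), plus M+1/M+2 isotope peaks at exact binomial 13C abundances for the
#' species' true carbon count, spaced by k x 1.003355 Da with a small uniform
#' ppm jitter. A seeded fraction of in-tissue pixels is dropped (off-tissue
#' pixels are absent spectra). Fully deterministic for a given spec.
#'
#' @param spec a [phantom_spec()].
#' @return list with `dataset` (an [msi_dataset()]), `truth` (data.table:
#'   `x`, `y`, `region`; region 0 = dropped pixel), and `species`
#'   (data.table: `region`, `class`, `carbons`, `double_bonds`, `adduct`,
#'   `name`, `formula`, `n_carbons_formula`, `mz`, `base_intensity`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  species <- list()
  for (ri in seq_along(spec$regions)) {
    p <- spec$regions[[ri]]$panel
    for (k in seq_len(nrow(p))) {
      f <- build_species(p$class[k], p$carbons[k], p$double_bonds[k])
      nm <- formula_mass(f)
      species[[length(species) + 1L]] <- data.table::data.table(
        region = ri, class = p$class[k], carbons = p$carbons[k],
        double_bonds = p$double_bonds[k], adduct = p$adduct[k],
        name = sprintf("[%s(%d:%d)%s]%s", p$class[k], p$carbons[k],
                       p$double_bonds[k], p$adduct[k],
                       if (ADDUCTS[[p$adduct[k]]]$z > 0) "+" else "-"),
        formula = format_formula(f),
        n_carbons_formula = as.integer(f[["C"]]),
        mz = adduct_mz(nm, p$adduct[k]),
        base_intensity = p$intensity[k])
    }
  }
  species <- data.table::rbindlist(species)

  n_x <- spec$grid[["n_x"]]; n_y <- spec$grid[["n_y"]]
  region_of <- matrix(0L, n_y, n_x)
  for (ri in seq_along(spec$regions)) region_of[spec$regions[[ri]]$mask] <- ri

  # log-normal multiplier with mean 1 and CV = noise_cv
  sig2 <- log(1 + spec$noise_cv^2)
  ln_mult <- function(n) {
    if (spec$noise_cv == 0) rep(1, n)
    else exp(stats::rnorm(n, mean = -sig2 / 2, sd = sqrt(sig2)))
  }

  orders <- spec$isotope_orders
  jit <- spec$isotope_jitter_ppm * 1e-6

  result <- withr_seed(spec$seed, {
    truth <- list(); spectra <- list()
    for (y in seq_len(n_y)) {
      for (x in seq_len(n_x)) {
        ri <- region_of[y, x]
        if (ri == 0L) next
        if (spec$dropout_fraction > 0 && stats::runif(1) < spec$dropout_fraction) {
          truth[[length(truth) + 1L]] <- data.table::data.table(
            x = x, y = y, region = 0L)
          next
        }
        sp <- species[species$region == ri, ]
        mzs <- numeric(0); ints <- numeric(0)
        for (k in seq_len(nrow(sp))) {
          ratios <- c(1, binomial_isotope_ratios(sp$n_carbons_formula[k]))
          for (ord in orders) {
            m <- sp$mz[k] + ord * C13_SPACING
            if (ord > 0 && jit > 0) m <- m * (1 + stats::runif(1, -jit, jit))
            mzs <- c(mzs, m)
            ints <- c(ints, sp$base_intensity[k] * ratios[ord + 1L] * ln_mult(1))
          }
        }
        ord_idx <- order(mzs)
        spectra[[length(spectra) + 1L]] <- msi_spectrum(mzs[ord_idx], ints[ord_idx],
                                                        x = x, y = y)
        truth[[length(truth) + 1L]] <- data.table::data.table(
          x = x, y = y, region = ri)
      }
    }
    list(truth = data.table::rbindlist(truth), spectra = spectra)
  })

  dataset <- msi_dataset(result$spectra, polarity = spec$mode)
  # keep declared grid extents even if border pixels are empty
  dataset$grid <- c(n_x = n_x, n_y = n_y)
  list(dataset = dataset, truth = result$truth, species = species)
}
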