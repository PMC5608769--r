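# Accurate-mass lipid annotation. A sum-composition library is generated
# combinatorially from lipid class construction tables, a fatty-acyl grid and
# per-polarity adduct sets; deisotoped features are then matched by signed ppm
# error, and feature pairs are searched for configured mass differences
# (oxidation, water loss, inter-adduct spacings).

# CODATA/AME monoisotopic atomic masses (Da)
ATOMIC_MASSES <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  Na = 22.9897692809,
  K  = 38.96370668,
  Cl = 34.96885268
)
ELECTRON_MASS <- 0.00054857990907

# Adduct definitions: element deltas plus charge sign (z). The ion m/z is the
# neutral mass plus the element masses minus z electrons, so the 0.55 mDa
# electron mass is accounted for -- it matters at < 3 ppm on small lipids.
ADDUCTS <- list(
  "+H"   = list(elements = c(H = 1),            z = +1, mode = "positive"),
  "+Na"  = list(elements = c(Na = 1),           z = +1, mode = "positive"),
  "+K"   = list(elements = c(K = 1),            z = +1, mode = "positive"),
  "+NH4" = list(elements = c(N = 1, H = 4),     z = +1, mode = "positive"),
  "-H"   = list(elements = c(H = -1),           z = -1, mode = "negative"),
  "+Cl"  = list(elements = c(Cl = 1),           z = -1, mode = "negative"),
  "+OAc" = list(elements = c(C = 2, H = 3, O = 2), z = -1, mode = "negative")
)

# Lipid class construction tables (all data-driven so users can audit or
# extend them). A species Class(C:D) is assembled as
#   backbone + extra + (acyl chains totalling C carbons, D double bonds)
#   - n_water x H2O
# where the pooled acyl contribution for n chains is C_c H_(2c-2d) O_(2n).
# For SM and Cer the C:D refers to the N-acyl chain; the sphingoid base is
# fixed at d18:1 (part of the backbone).
LIPID_CLASSES <- list(
  FFA    = list(n_chains = 1, backbone = c(),                          n_water = 0, modes = "negative"),
  DAG    = list(n_chains = 2, backbone = c(C = 3, H = 8, O = 3),       n_water = 2, modes = "positive"),
  TAG    = list(n_chains = 3, backbone = c(C = 3, H = 8, O = 3),       n_water = 3, modes = "positive"),
  PC     = list(n_chains = 2, backbone = c(C = 8, H = 20, N = 1, O = 6, P = 1), n_water = 2, modes = c("positive", "negative")),
  LysoPC = list(n_chains = 1, backbone = c(C = 8, H = 20, N = 1, O = 6, P = 1), n_water = 1, modes = "positive"),
  PE     = list(n_chains = 2, backbone = c(C = 5, H = 14, N = 1, O = 6, P = 1), n_water = 2, modes = c("positive", "negative")),
  PS     = list(n_chains = 2, backbone = c(C = 6, H = 14, N = 1, O = 8, P = 1), n_water = 2, modes = c("positive", "negative")),
  PA     = list(n_chains = 2, backbone = c(C = 3, H = 9, O = 6, P = 1), n_water = 2, modes = "negative"),
  PG     = list(n_chains = 2, backbone = c(C = 6, H = 15, O = 8, P = 1), n_water = 2, modes = "negative"),
  PI     = list(n_chains = 2, backbone = c(C = 9, H = 19, O = 11, P = 1), n_water = 2, modes = "negative"),
  CE     = list(n_chains = 1, backbone = c(C = 27, H = 46, O = 1),     n_water = 1, modes = "positive"),
  SM     = list(n_chains = 1, backbone = c(C = 18, H = 37, N = 1, O = 2),
                extra = c(C = 5, H = 12, N = 1, O = 3, P = 1),         n_water = 1, modes = "positive"),
  Cer    = list(n_chains = 1, backbone = c(C = 18, H = 37, N = 1, O = 2), n_water = 1, modes = "positive")
)

default_classes <- function(mode) {
  names(LIPID_CLASSES)[vapply(LIPID_CLASSES, function(cl) mode %in% cl$modes, logical(1))]
}

default_adducts <- function(mode) {
  names(ADDUCTS)[vapply(ADDUCTS, function(a) a$mode == mode, logical(1))]
}

#' Parse an elemental formula string
#'
#' @param x formula like `"C42H82NO8P"` (elements C, H, N, O, P, Na, K, Cl;
#'   an omitted count means 1).
#' @return named integer vector of element counts.
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)
  parts <- regmatches(x, m)[[1]]
  parts <- parts[nzchar(parts)]
  counts <- integer(0)
  for (p in parts) {
    el <- sub("[0-9]*$", "", p)
    n <- sub("^[A-Za-z]+", "", p)
    n <- if (nzchar(n)) as.integer(n) else 1L
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  if (!all(names(counts) %in% names(ATOMIC_MASSES))) {
    bad <- setdiff(names(counts), names(ATOMIC_MASSES))
    stop(sprintf("unknown element(s): %s", paste(bad, collapse = ", ")), call. = FALSE)
  }
  counts
}

format_formula <- function(counts) {
  counts <- counts[counts != 0]
  ord <- c("C", "H", "N", "O", "P", "Na", "K", "Cl")
  counts <- counts[order(match(names(counts), ord))]
  paste0(names(counts), ifelse(counts == 1, "", counts), collapse = "")
}

#' Monoisotopic mass of an elemental formula
#'
#' Sum of element counts times monoisotopic atomic masses (12C defines the
#' mass scale at exactly 12 Da).
#'
#' @param formula named numeric vector of element counts, or a formula string
#'   accepted by [parse_formula()].
#' @return monoisotopic mass in Da.
#' @examples
#' formula_mass("H2O")          # 18.0106
#' formula_mass(c(C = 1))       # 12 exactly
#' @export
formula_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  if (!length(formula) || all(formula == 0)) {
    stop("formula must contain at least one atom", call. = FALSE)
  }
  if (!all(names(formula) %in% names(ATOMIC_MASSES))) {
    bad <- setdiff(names(formula), names(ATOMIC_MASSES))
    stop(sprintf("unknown element(s): %s", paste(bad, collapse = ", ")), call. = FALSE)
  }
  sum(formula * ATOMIC_MASSES[names(formula)])
}

add_counts <- function(a, b) {
  els <- union(names(a), names(b))
  out <- stats::setNames(numeric(length(els)), els)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  out
}

#' Neutral elemental formula of a sum-composition lipid species
#'
#' Assembles the formula from the class construction table: backbone (plus
#' any head-group extra) + pooled acyl chains (`C:D` totals) minus one H2O
#' per ester or amide bond. Feasibility requires `total_double_bonds >= 0`
#' and at most `(total_carbons - 2 * n_chains) / 2` (each chain needs at
#' least two carbons and double bonds are capped by chain length).
#'
#' @param lipid_class one of `names(lipid_classes())`.
#' @param total_carbons,total_double_bonds acyl totals for the species. For
#'   SM and Cer these describe the N-acyl chain only (sphingoid base fixed at
#'   d18:1).
#' @return named integer vector of element counts (neutral molecule).
#' @examples
#' format_formula(build_species("PC", 34, 1))   # "C42H82NO8P"
#' @export
build_species <- function(lipid_class, total_carbons, total_double_bonds) {
  if (!lipid_class %in% names(LIPID_CLASSES)) {
    stop(sprintf("unsupported lipid class: %s", lipid_class), call. = FALSE)
  }
  cl <- LIPID_CLASSES[[lipid_class]]
  c_tot <- as.integer(total_carbons); d_tot <- as.integer(total_double_bonds)
  if (c_tot < 2L * cl$n_chains || d_tot < 0L || d_tot > (c_tot - 2L * cl$n_chains) / 2) {
    stop(sprintf("infeasible composition %s(%d:%d)", lipid_class, c_tot, d_tot),
         call. = FALSE)
  }
  acyl <- c(C = c_tot, H = 2L * c_tot - 2L * d_tot, O = 2L * cl$n_chains)
  f <- add_counts(cl$backbone, acyl)
  if (!is.null(cl$extra)) f <- add_counts(f, cl$extra)
  f <- add_counts(f, c(H = -2 * cl$n_water, O = -1 * cl$n_water))
  if (any(f < 0)) stop("internal: negative element count", call. = FALSE)
  f[f != 0]
}

#' m/z of an adduct ion
#'
#' `neutral_mass` plus the adduct's element masses, corrected for the
#' electron gained or lost with the charge.
#'
#' @param neutral_mass neutral monoisotopic mass (Da), > 0; vectorised.
#' @param adduct adduct name: `"+H"`, `"+Na"`, `"+K"`, `"+NH4"`, `"-H"`,
#'   `"+Cl"`, `"+OAc"`.
#' @return ion m/z (Th).
#' @export
adduct_mz <- function(neutral_mass, adduct) {
  if (!is.numeric(neutral_mass) || any(neutral_mass <= 0)) {
    stop("neutral_mass must be positive", call. = FALSE)
  }
  if (!adduct %in% names(ADDUCTS)) {
    stop(sprintf("unknown adduct: %s", adduct), call. = FALSE)
  }
  a <- ADDUCTS[[adduct]]
  delta <- sum(a$elements * ATOMIC_MASSES[names(a$elements)]) - a$z * ELECTRON_MASS
  neutral_mass + delta
}

#' Default fatty-acyl chain grid
#'
#' Even-carbon chains C12--C24 with 0--6 double bonds, capped at
#' `(c - 2) / 2` double bonds per chain: the range covering the common
#' mammalian fatty acids.
#'
#' @return data.table with columns `c` (carbons) and `d` (double bonds).
#' @export
default_fa_grid <- function() {
  g <- data.table::CJ(c = seq(12L, 24L, 2L), d = 0:6)
  g[g$d <= (g$c - 2L) / 2, ]
}

#' Supported lipid classes and their construction tables
#' @return named list of class tables (chains, backbone, waters, modes).
#' @export
lipid_classes <- function() LIPID_CLASSES

# Distinct (C, D) totals reachable by n chains drawn (with repetition) from
# the grid.
sum_compositions <- function(n_chains, fa_grid = default_fa_grid()) {
  tot <- unique(data.table::as.data.table(fa_grid)[, .(c, d)])
  acc <- tot
  if (n_chains > 1L) {
    for (i in seq_len(n_chains - 1L)) {
      acc <- unique(data.table::CJ(i = seq_len(nrow(acc)), j = seq_len(nrow(tot)))[
        , .(c = acc$c[i] + tot$c[j], d = acc$d[i] + tot$d[j])])
    }
  }
  data.table::setorder(acc, c, d)
  acc
}

#' Generate the combinatorial lipid m/z library
#'
#' Cartesian product of lipid classes (defaults depend on polarity), feasible
#' sum compositions from the fatty-acyl grid, and polarity-matched adducts.
#' Entries are deduplicated on (class, carbons, double bonds, adduct) and
#' sorted by m/z; generation is deterministic and independent of the listing
#' order of the configuration.
#'
#' Default positive-mode classes: DAG, TAG, PC, PE, PS, LysoPC, CE, SM, Cer
#' with adducts +K, +H, +Na, +NH4. Default negative-mode classes: PC, PA, PE,
#' PS, PG, PI, FFA with adducts -H, +Cl, +OAc.
#'
#' @param mode `"positive"` or `"negative"`.
#' @param classes character vector of class names (default: the mode's set).
#' @param adducts character vector of adduct names (default: the mode's set).
#' @param fa_grid chain grid as from [default_fa_grid()].
#' @return data.table of class `msi_library`: `class`, `carbons`,
#'   `double_bonds`, `adduct`, `name`, `formula`, `neutral_mass`, `mz`,
#'   `mode`, sorted by `mz`.
#' @export
build_library <- function(mode = c("positive", "negative"), classes = NULL,
                          adducts = NULL, fa_grid = default_fa_grid()) {
  mode <- match.arg(mode)
  if (is.null(classes)) classes <- default_classes(mode)
  if (is.null(adducts)) adducts <- names(ADDUCTS)[
    vapply(ADDUCTS, function(a) a$mode == mode, logical(1))]
  if (!length(classes)) stop("empty class list", call. = FALSE)
  if (!length(adducts)) stop("empty adduct list", call. = FALSE)
  bad <- setdiff(classes, names(LIPID_CLASSES))
  if (length(bad)) stop(sprintf("unsupported lipid class: %s", bad[1]), call. = FALSE)
  bad <- setdiff(adducts, names(ADDUCTS))
  if (length(bad)) stop(sprintf("unknown adduct: %s", bad[1]), call. = FALSE)
  wrong_mode <- adducts[vapply(adducts, function(a) ADDUCTS[[a]]$mode != mode, logical(1))]
  if (length(wrong_mode)) {
    stop(sprintf("adduct %s is not a %s-mode adduct", wrong_mode[1], mode), call. = FALSE)
  }
  classes <- sort(unique(classes))
  adducts <- sort(unique(adducts))

  rows <- list()
  for (cls in classes) {
    comps <- sum_compositions(LIPID_CLASSES[[cls]]$n_chains, fa_grid)
    for (k in seq_len(nrow(comps))) {
      f <- build_species(cls, comps$c[k], comps$d[k])
      nm <- formula_mass(f)
      for (ad in adducts) {
        rows[[length(rows) + 1L]] <- data.table::data.table(
          class = cls, carbons = comps$c[k], double_bonds = comps$d[k],
          adduct = ad,
          name = sprintf("[%s(%d:%d)%s]%s", cls, comps$c[k], comps$d[k], ad,
                         if (ADDUCTS[[ad]]$z > 0) "+" else "-"),
          formula = format_formula(f), neutral_mass = nm,
          mz = adduct_mz(nm, ad), mode = mode)
      }
    }
  }
  lib <- unique(data.table::rbindlist(rows),
                by = c("class", "carbons", "double_bonds", "adduct"))
  data.table::setorder(lib, mz)
  data.table::setattr(lib, "class", c("msi_library", class(lib)))
  lib[]
}

#' Annotate features by accurate mass
#'
#' Reports every (feature, library entry) pair whose signed relative mass
#' error `1e6 * (feature_mz - entry_mz) / entry_mz` is within
#' `ppm_tolerance`. A feature may carry several annotations (isobars) and a
#' library entry may match several features. The table is sorted by feature
#' m/z, then absolute ppm error.
#'
#' @param features an `msi_features` table (or anything with an `mz` column).
#' @param library an `msi_library` from [build_library()].
#' @param ppm_tolerance match window in ppm (> 0); the paper-scale defaults
#'   are a few ppm for Orbitrap-class data.
#' @return data.table: `feature_mz`, `class`, `carbons`, `double_bonds`,
#'   `adduct`, `name`, `formula`, `library_mz`, `ppm_error`.
#' @export
annotate_features <- function(features, library, ppm_tolerance = 5) {
  check_scalar_number(ppm_tolerance, "ppm_tolerance", lower = 0, strict_lower = TRUE)
  fmz <- if (is.data.frame(features)) features$mz else as.numeric(features)
  lib <- data.table::as.data.table(library)
  data.table::setorder(lib, mz)
  out <- list()
  w <- ppm_tolerance * 1e-6
  for (m in fmz) {
    # |1e6 (m - L)/L| <= tol  <=>  L in [m/(1+w), m/(1-w)]
    lo <- findInterval(m / (1 + w), lib$mz, left.open = TRUE) + 1L
    hi <- findInterval(m / (1 - w), lib$mz)
    if (hi < lo) next
    idx <- seq.int(lo, hi)
    ppm <- 1e6 * (m - lib$mz[idx]) / lib$mz[idx]
    keep <- abs(ppm) <= ppm_tolerance
    if (any(keep)) {
      sel <- lib[idx[keep], .(class, carbons, double_bonds, adduct, name,
                              formula, library_mz = mz)]
      sel[, `:=`(feature_mz = m, ppm_error = ppm[keep])]
      out[[length(out) + 1L]] <- sel
    }
  }
  res <- if (length(out)) data.table::rbindlist(out) else
    data.table::data.table(class = character(), carbons = integer(),
                           double_bonds = integer(), adduct = character(),
                           name = character(), formula = character(),
                           library_mz = numeric(), feature_mz = numeric(),
                           ppm_error = numeric())
  data.table::setcolorder(res, c("feature_mz", "class", "carbons", "double_bonds",
                                 "adduct", "name", "formula", "library_mz",
                                 "ppm_error"))
  res[order(feature_mz, abs(ppm_error))]
}

#' Default mass-difference list for difference matching
#'
#' Oxidation (+O, +2O), water loss, and the potassium/sodium vs proton
#' adduct spacings; all values in Da. The list is plain data users can
#' replace or extend.
#'
#' @return data.table with columns `name`, `delta`.
#' @export
default_difference_list <- function() {
  o <- ATOMIC_MASSES[["O"]]; h2o <- formula_mass("H2O")
  data.table::data.table(
    name = c("oxidation(+O)", "oxidation(+2O)", "water-loss", "K/H", "Na/H"),
    delta = c(o, 2 * o, h2o,
              ATOMIC_MASSES[["K"]] - ATOMIC_MASSES[["H"]],
              ATOMIC_MASSES[["Na"]] - ATOMIC_MASSES[["H"]]))
}

#' Search feature pairs for configured mass differences
#'
#' Finds all ordered feature pairs (a, b) with `mz_b > mz_a` whose spacing
#' matches a named mass delta within `ppm_tolerance` ppm of `mz_b`:
#' fragmentation- or modification-related pairs such as oxidation products.
#'
#' @param features `msi_features` table or numeric m/z vector.
#' @param deltas data.table (`name`, `delta`), e.g.
#'   [default_difference_list()].
#' @param ppm_tolerance window in ppm of the heavier member.
#' @return data.table: `mz_a`, `mz_b`, `delta_name`, `delta`, `error_mda`.
#' @export
difference_match <- function(features, deltas = default_difference_list(),
                             ppm_tolerance = 5) {
  deltas <- data.table::as.data.table(deltas)
  if (!nrow(deltas)) stop("delta list must be non-empty", call. = FALSE)
  check_scalar_number(ppm_tolerance, "ppm_tolerance", lower = 0, strict_lower = TRUE)
  mzs <- sort(if (is.data.frame(features)) features$mz else as.numeric(features))
  out <- list()
  n <- length(mzs)
  for (k in seq_len(nrow(deltas))) {
    for (i in seq_len(n)) {
      target <- mzs[i] + deltas$delta[k]
      js <- which(mzs > mzs[i] & abs(mzs - target) <= ppm_tolerance * 1e-6 * mzs)
      for (j in js) {
        out[[length(out) + 1L]] <- data.table::data.table(
          mz_a = mzs[i], mz_b = mzs[j], delta_name = deltas$name[k],
          delta = deltas$delta[k],
          error_mda = 1e3 * (mzs[j] - mzs[i] - deltas$delta[k]))
      }
    }
  }
  if (length(out)) data.table::rbindlist(out) else
    data.table::data.table(mz_a = numeric(), mz_b = numeric(),
                           delta_name = character(), delta = numeric(),
                           error_mda = numeric())
}
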