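# Shared fixtures and independent oracles. Oracles deliberately re-derive
# expected values through a different code path than the implementation.

# -- independent monoisotopic mass oracle ------------------------------------
# Own atomic mass table and a character-walking parser, written before and
# independently of the package's formula machinery.
ORACLE_MASSES <- list(C = 12, H = 1.00782503207, N = 14.0030740048,
                      O = 15.9949146196, P = 30.97376163, Na = 22.9897692809,
                      K = 38.96370668, Cl = 34.96885268)
ORACLE_ELECTRON <- 0.00054857990907

oracle_mass <- function(formula) {
  chars <- strsplit(formula, "")[[1]]
  total <- 0
  i <- 1
  while (i <= length(chars)) {
    el <- chars[i]; i <- i + 1
    if (i <= length(chars) && grepl("[a-z]", chars[i])) {
      el <- paste0(el, chars[i]); i <- i + 1
    }
    digits <- ""
    while (i <= length(chars) && grepl("[0-9]", chars[i])) {
      digits <- paste0(digits, chars[i]); i <- i + 1
    }
    n <- if (nzchar(digits)) as.integer(digits) else 1L
    total <- total + n * ORACLE_MASSES[[el]]
  }
  total
}

# ion m/z oracle: neutral formula + adduct atoms, electron-corrected
ORACLE_ADDUCT <- list(
  "+H"   = list(atoms = "H",      sign = +1, z = +1),
  "+Na"  = list(atoms = "Na",     sign = +1, z = +1),
  "+K"   = list(atoms = "K",      sign = +1, z = +1),
  "+NH4" = list(atoms = "NH4",    sign = +1, z = +1),
  "-H"   = list(atoms = "H",      sign = -1, z = -1),
  "+Cl"  = list(atoms = "Cl",     sign = +1, z = -1),
  "+OAc" = list(atoms = "C2H3O2", sign = +1, z = -1))

oracle_ion_mz <- function(formula, adduct) {
  a <- ORACLE_ADDUCT[[adduct]]
  oracle_mass(formula) + a$sign * oracle_mass(a$atoms) - a$z * ORACLE_ELECTRON
}

# -- tiny dataset builders ---------------------------------------------------
# 2x2 grid, 3 peaks per pixel, distinct intensities per pixel
tiny_dataset <- function() {
  mk <- function(x, y, base) {
    msi_spectrum(c(400.0, 500.5, 600.25), base * c(1, 2, 3), x = x, y = y)
  }
  msi_dataset(list(mk(1, 1, 10), mk(2, 1, 20), mk(1, 2, 30), mk(2, 2, 40)),
              polarity = "positive")
}

# feature matrix built directly (bypassing binning) for normalisation /
# multivariate / imaging tests
direct_matrix <- function(intensities, mzs = NULL, pixels = NULL) {
  nf <- nrow(intensities)
  np <- ncol(intensities)
  if (is.null(mzs)) mzs <- 400 + seq_len(nf)
  if (is.null(pixels)) pixels <- data.table::data.table(x = seq_len(np), y = 1L)
  feats <- data.table::data.table(
    feature_id = seq_len(nf), bin = seq_len(nf), mz = mzs,
    bin_lo = mzs - 0.002, bin_hi = mzs + 0.002,
    n_ions = np, n_pixels = np, detection_fraction = 1)
  data.table::setattr(feats, "anchor_mz", min(mzs))
  data.table::setattr(feats, "bin_ppm", 10)
  lipidmsi:::new_msi_matrix(feats, intensities, pixels)
}

# brute-force O(n^2) deisotoping oracle implementing the same contract
# (ascending-m/z greedy parents, per-candidate band test, split-envelope
# group rescue) as an independent double loop.
oracle_deisotope <- function(mzs, means, ppm_window = 10, tolerance = 0.5,
                             c_per_da = 0.055, p13 = 0.0111) {
  n <- length(mzs)
  removed <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (removed[i] || means[i] <= 0) next
    nC <- max(1, round(c_per_da * mzs[i]))
    for (ord in 1:2) {
      r_exp <- if (ord == 1) nC * p13 else choose(nC, 2) * p13^2
      cand <- c()
      for (j in seq_len(n)) {
        if (j > i && !removed[j] &&
            abs(mzs[j] - (mzs[i] + ord * 1.003355)) <= ppm_window * 1e-6 * mzs[i]) {
          cand <- c(cand, j)
        }
      }
      if (!length(cand)) next
      obs <- means[cand] / means[i]
      band <- function(r) r_exp > 0 && r >= r_exp * (1 - tolerance) &&
        r <= r_exp * (1 + tolerance)
      ok <- sapply(obs, band)
      if (length(cand) > 1 && !all(ok) && band(sum(obs))) ok[] <- TRUE
      removed[cand[ok]] <- TRUE
    }
  }
  which(removed)
}
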