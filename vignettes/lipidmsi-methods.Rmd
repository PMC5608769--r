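---
title: "lipidmsi: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lipidmsi: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidmsi)
```

# The problem

MALDI mass spectrometry imaging (MSI) acquires a full mass spectrum at every
pixel of a tissue raster. For lipidomics the analyst wants three things from
such a dataset: per-lipid ion images, putative identities for the observed
ions, and an unsupervised segmentation of the tissue into regions of similar
lipid composition. `lipidmsi` implements that workflow end to end on imzML
input: threshold extraction, ppm binning into a feature × pixel matrix,
detection filtering, ¹³C deisotoping, accurate-mass annotation against a
combinatorially generated lipid library, per-pixel normalisation, centering +
Pareto scaling, PCA and k-means segmentation, and 2-D image slicing — plus a
synthetic phantom generator so every stage can be validated against known
ground truth.

The package assumes **centroided** peak lists. Profile-mode peak picking,
baseline correction and recalibration are out of scope; if your imzML holds
profile spectra, centroid upstream.

# Pipeline model, stage by stage

## Peak extraction and mass binning

Ions with intensity strictly above `intensity_threshold` (default 0 — keep
every nonzero centroid) are pooled across pixels and grouped on a fixed
**ppm ladder** anchored at the smallest observed m/z $m_0$: bin $k$ spans
$[m_0(1+kw),\, m_0(1+(k+1)w))$ with $w = \texttt{bin\_ppm}\times10^{-6}$.
The ladder is deterministic, independent of ion order, and partitions the
ion multiset exactly. Bin width equals `bin_ppm` ppm at the anchor mass and
is slightly narrower (in relative terms) at higher m/z, which only makes
grouping more conservative. The default `bin_ppm = 10` suits ~60,000
resolving power at m/z 400; widen it for time-of-flight data, narrow it for
higher-resolution acquisitions.

A bin becomes a **feature** whose m/z is the median of its member ions. The
detection fraction is the number of distinct pixels contributing an ion to
the bin divided by the number of *acquired* spectra — off-tissue pixels
with no spectrum do not dilute detection. Features with detection fraction
strictly above `min_fraction` (default 0.01, a deliberately permissive
1%-of-pixels floor) are kept. When one pixel has several ions in one bin,
the matrix entry is their **sum**, not their maximum, so total ion count is
conserved and TIC normalisation downstream stays meaningful.

## Deisotoping

A lipid molecular ion M is accompanied by ¹³C satellites at roughly
M+1.003355 and M+2.006710. The expected satellite intensity is predicted
from an approximate carbon count estimated linearly from m/z:
$n_C = \mathrm{round}(0.055 \cdot m/z)$, where 0.055 carbons per Dalton is
the carbon density of glycerophospholipids. The linearised binomial
abundances are $r_1 = n_C\,p$ and $r_2 = \binom{n_C}{2}p^2$ with
$p = 0.0111$; both are ratios relative to the monoisotopic peak and $r_1$
may legitimately exceed 1 above ~90 carbons.

Features are scanned in ascending m/z. Each unclaimed feature acts as a
parent; heavier features within `ppm_window` (default 10 ppm) of the M+1 or
M+2 position whose mean-intensity ratio to the parent lies within
`tolerance` (default ±50%) of the expected ratio are removed. A feature
claimed as an isotope never serves as a parent, because the monoisotopic
peak is always the lightest of its envelope. Ratios are computed on the
mean spectrum of a seeded random pixel subset (default
`min(500, n_pixels)`), which is robust to single-pixel noise. M+1 and M+2
are tested independently of each other.

**Split envelopes.** The fixed ladder can cut one isotope peak population
in two when its (jittered or drifting) m/z straddles a bin boundary; each
half then carries only part of the envelope intensity and fails the band
individually. When several candidates share one isotope window and their
*summed* ratio fits the band, `lipidmsi` removes the whole group
(`via_group = TRUE` in the report). Without this rule, roughly one isotope
in six on the default phantom survives deisotoping purely because of bin
placement; with it, recall on ground-truthed phantoms is ≥ 95% with zero
false removals of monoisotopic features in our tests.

## Lipid library and annotation

The library is the Cartesian product of lipid classes, feasible
sum-compositions, and polarity-matched adducts. Positive mode searches DAG,
TAG, PC, PE, PS, LysoPC, CE, SM and Cer with +H, +Na, +K and +NH₄; negative
mode searches PC, PA, PE, PS, PG, PI and FFA with −H, +Cl and +OAc. Species
are built at **sum-composition** level — Class(C:D), total acyl carbons and
double bonds — which is all accurate mass can distinguish; sn-positional
isomers are not resolved. Construction is table-driven
(backbone + pooled acyl chains − one H₂O per ester/amide bond; see
`lipid_classes()`) so the tables can be audited or extended. For SM and Cer
the C:D indexes the N-acyl chain with the sphingoid base fixed at d18:1.

The default fatty-acyl grid is even carbons 12–24 with 0–6 double bonds
capped at $(c-2)/2$ per chain — the common mammalian fatty acids. The grid
yields ~8,000 library entries over both modes. Ion m/z values use CODATA
monoisotopic atomic masses and include the electron mass in the adduct
delta; at sub-3-ppm matching the 0.55 mDa electron matters.

Annotation reports every (feature, entry) pair within `ppm_tolerance`
(default 5 ppm) as a *putative* match: isobars give multiple annotations
per feature by design, and accurate mass alone never confirms an identity —
MS/MS confirmation is outside this package. Difference matching searches
deisotoped feature pairs for configurable mass deltas (default: +O, +2O
oxidation, water loss, K/H and Na/H adduct spacings) to flag
fragmentation- and modification-related pairs.

## Normalisation and scaling

Per-pixel factors: total ion count (default), median of the pixel's
**nonzero** intensities, or the mean intensity of user-supplied standard
ions. The nonzero restriction for the median matters because sparse MSI
columns are zero-dominated; a median of zero would be degenerate. Pixels
with a zero factor are left all-zero and counted in a warning rather than
dropped.

Before PCA, rows are mean-centered and Pareto-scaled — divided by
$\sqrt{s_i}$ with $s_i$ the sample (n−1) standard deviation — damping the
dominance of intense lipids while preserving more variance structure than
unit-variance scaling. Zero-variance rows are zeroed, not dropped, to keep
feature indexing stable.

## Multivariate segmentation

Pixels are observations and features are variables: clustering pixels is
what turns spectra into a segmentation image. PCA is computed by SVD of the
pixels × features matrix; the sign of each component is fixed so its
largest-magnitude loading is positive, making score images bit-for-bit
reproducible. k-means uses Lloyd's algorithm with seeded **k-means++**
initialisation and 5 deterministic restarts, keeping the solution with the
lowest within-cluster sum of squares. A single uniformly drawn
pixel-sample initialisation (available as `init = "sample"`) was measured
to fall into 2-centers-in-1-region local optima on the three-region phantom
for many seeds (ARI ≈ 0.45), so it is not the default; with k-means++ and
restarts the phantom is segmented at ARI ≥ 0.95 across seeds in our tests.
`k` has no default — the expected region count is tissue-specific. By
default k-means runs on normalised (unscaled) intensities; set
`kmeans_scaled = TRUE` to cluster on the Pareto-scaled matrix instead.

## Imaging

"Slicing" reshapes one value per acquired pixel onto the acquisition grid:
value of pixel (x, y) lands at row y, column x, so y increases downwards
and x to the right. Missing pixels carry NA — never 0, which is a valid
intensity — and render as background. Rasters are written as PNG (graphics
device) or plain-text PPM; PPM output is byte-deterministic and trivially
machine-readable, which is what the test suite checks colors against. An
RGB overlay of up to three ion images mirrors the usual multi-marker
composite.

# The phantom: what it does and does not emulate

`default_phantom_spec()` states a cerebellum-like world: a rectangular
tissue slab on an off-tissue border, three horizontal-band regions, each
expressing four lipid adduct ions (12 species spanning nine classes and all
four positive adducts), multiplicative log-normal noise with unit mean and
20% CV, 5% random pixel dropout, and full M/M+1/M+2 envelopes at **exact
binomial** ¹³C abundances for each species' true carbon count, spaced
1.003355 Da apart with ±1 ppm uniform jitter to exercise the binning
tolerance. Generation is fully seed-deterministic down to byte-identical
imzML output, and the ground truth (pixel regions, species, exact m/z) is
returned alongside.

The phantom deliberately does **not** simulate matrix-cluster chemical
noise, baseline, mass-calibration drift, spot-size physics, isobaric
overlap beyond what the library itself produces, or intensity gradients
within a region. A green end-to-end test therefore establishes that the
implementation is internally correct against a known world — not that the
default parameters are optimal for any particular instrument or tissue.

# Numerical choices

* Monoisotopic masses: CODATA/AME values, ¹²C = 12 exactly; electron mass
  included in adduct deltas. Library m/z is checked against an independent
  per-element summation oracle to < 1e-4 Da in the tests.
* Bin indices computed as `floor((mz/m0 - 1)/w + 1e-12)`; the 1e-12 nudge
  keeps ions that land exactly on a boundary (to double precision) in the
  lower bin rather than letting representation error flip them.
* Half-open bins: an ion exactly at `bin_hi` belongs to the next bin.
* k-means convergence: maximum center shift < 1e-6, cap 100 iterations per
  restart; ties in assignment break to the lowest cluster index.
* Degenerate inputs: empty datasets round-trip as empty; empty pixels and
  zero-variance features are zeroed and warned about, never silently
  dropped; empty clusters are emitted with zero centers and flagged.
* All seeded operations (pixel subsetting, k-means, phantom generation)
  restore the caller's RNG state.

# Known limitations

Singly charged ions only (MALDI lipids are predominantly 1+); no
full-pattern isotope fitting (averagine-style deconvolution); no
FDR-controlled annotation; no spatially aware clustering; continuous-mode
imzML is read but never written; 3-D MSI is unsupported.
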