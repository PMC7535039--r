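---
title: "Habitat radiomics of paired tumor subregions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat radiomics of paired tumor subregions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetrad)
library(dplyr)
```

## The scientific question

When a tumor recurs inside the irradiated volume after radiotherapy, the
recurrence often grows from a subregion of the original tumor that was more
radio-resistant than the rest. If such subregions ("habitats") differ in
their imaging phenotype *before* treatment, a radiomic analysis of the
pre-treatment scan could flag them in advance and guide selective dose
escalation ("dose painting").

`hetrad` implements the paired design this question leads to. For each
subject, the pre-treatment tumor volume (GTV) is partitioned into:

* the **recurrent habitat**: the recurrence volume (GTVr), contoured at the
  time of recurrence and mapped back onto the pre-treatment image, clipped
  to the GTV;
* the **non-recurrent habitat**: the set difference GTV − GTVr.

Each habitat yields a vector of 47 radiomic features, and the two vectors
per subject form a paired sample. The statistical stage asks which features
differ systematically between habitats across subjects.

A recurrence is called *in-field* when at least 95% of GTVr lies inside the
95% isodose region of the delivered plan; the comparison is inclusive
(`overlap >= 0.95`). The pipeline logs the verdict per subject but does not
exclude out-of-field subjects unless strict mode is requested: the cohort
filter is a study decision, not a property of the computation.

## The feature set

Per habitat, 47 features in five families:

* **Intensity histogram (7)** — computed on the *raw* intensities: mean,
  variance, skewness, kurtosis, mean absolute deviation, hyperskewness,
  hyperflatness. All moments are population moments (divide by N).
  Kurtosis is the raw fourth standardized moment (3 for a Gaussian), and
  hyperskewness/hyperflatness are the fifth and sixth standardized central
  moments — for a Gaussian they converge to 0 and 15, which the test suite
  verifies by simulation.
* **GLCM (9)** — gray-level co-occurrence probabilities over all 13 unique
  3D directions at Chebyshev distance 1, both orderings (symmetric matrix),
  only pairs fully inside the ROI: energy, contrast, entropy (log2),
  homogeneity, correlation, sum average, variance, dissimilarity,
  autocorrelation.
* **GLRLM (13)** — maximal equal-level runs along the 13 directions,
  accumulated into one matrix: SRE, LRE, GLN, RLN, RP, LGRE, HGRE, SRLGE,
  SRHGE, LRLGE, LRHGE, GLV, RLV. Because all 13 directions scan every
  voxel, the run-length mass is 13 times the voxel count; run percentage is
  therefore defined as runs divided by that mass, so an ROI of all
  length-1 runs has RP = 1 regardless of direction count.
* **GLSZM (13)** — 26-connected components of equal level: SZE, LZE, GLN,
  ZSN, ZP, LGZE, HGZE, SZLGE, SZHGE, LZLGE, LZHGE, GLV, ZSV. Zone
  percentage is zones per ROI voxel.
* **NGTDM (5)** — Amadasun–King coarseness, contrast, busyness, complexity,
  strength, from the per-level summed absolute deviation of each voxel from
  the mean of its in-ROI 26-neighborhood. All denominators carry an
  epsilon guard of 1e-6, so a perfectly uniform ROI has coarseness 1e6
  rather than infinity; the guard value is recorded in every run report.

Texture is computed on the voxel grid, ignoring the physical anisotropy of
the voxels (0.7 × 0.7 × 5 mm by default). This matches the established
toolbox convention for this analysis; isotropic resampling would change
absolute feature values and is deliberately out of scope.

Every matrix builder is verified against an independently written
brute-force implementation (plain triple loops) on dozens of random small
ROIs, exactly for counts and to 1e-10 for probabilities.

## Gray-level discretization

Texture features operate on quantized gray levels. Each habitat is
discretized independently to `Ng = 256` levels with a Lloyd–Max scalar
quantizer — the MSE-optimal quantizer for the habitat's own intensity
distribution — rather than an equal-width binning. The implementation
alternates centroid updates (conditional means) and boundary updates
(midpoints), stopping when the largest centroid move falls below 1e-8 or
after 500 iterations. Design choices that required a decision:

* **Initialization** is an equally spaced codebook over the data range.
  The first iteration then scores exactly the equal-width quantizer, and
  since the Lloyd map never increases MSE, the converged codebook is
  guaranteed at least as good as the uniform baseline. We found that the
  plausible alternative — equal-probability (quantile) initialization —
  converges to local optima that can be *worse* than the uniform quantizer
  on real-looking intensity distributions, because it over-allocates cells
  to dense intensity regions and Lloyd iterations only move cells locally.
* **Empty cells** inherit the midpoint of their neighbors' centroids, so
  the level count stays at `Ng`.
* **Low-cardinality ROIs**: when the ROI has `d <= Ng` distinct values,
  each distinct value gets its own level and the MSE is exactly zero; the
  remaining levels are parked above the data range.
* **Per-ROI codebooks**: each habitat is quantized against its own
  distribution. This makes texture features scale-free per region; the
  shared-scale comparison between habitats happens in the histogram stage,
  which uses common bin edges across both habitats (64 bins by default,
  normalized to relative frequency).

The MSE trace is monotone non-increasing by construction and asserted in
tests; quantization is invariant to the ordering of the input voxels.

## The paired statistical stage

For each feature `f`, the per-subject difference
`d_f(k) = f(recurrent, k) − f(nonrecurrent, k)` is computed. Each
difference column is tested for normality with Shapiro–Wilk at 0.05; a
normal-looking column gets a paired t-test, otherwise a Wilcoxon
signed-rank test (zeros dropped, exact distribution for n ≤ 25 without
ties, normal approximation with continuity correction otherwise). The
significance cut is Bonferroni-corrected: `alpha / 47`, used unrounded for
selection (0.05/47 = 0.00106…, displayed as 0.001).

Downstream of selection:

* **Correlation**: Pearson correlations with p-values between the
  significant features' difference columns, masked at unadjusted p < 0.05.
* **PCA**: the pooled 2n region vectors (n recurrent + n non-recurrent),
  restricted to the significant features, are z-scored per column and
  decomposed. Standardization matters because the features span many
  orders of magnitude. Components are ordered by explained variance and
  sign-fixed so the largest-magnitude loading is positive. Separation of
  the two region groups is summarized by the mean silhouette of the PC1
  scores.

If no feature survives Bonferroni, correlation and PCA fall back to the
top 7 features by p-value, with an explicit warning in the result and the
run report.

Calibration of this select-then-report pipeline is checked by simulation:
over 1000 null cohorts (n = 14 subjects, 47 independent N(0,1) difference
columns), the family-wise rejection rate stays at or below 0.06 — slightly
conservative, as expected from Bonferroni plus the slightly conservative
exact signed-rank branch.

## The synthetic phantom

No patient imaging ships with the package; a generator produces MRI-like
paired-habitat phantoms. Per subject:

* a 64 × 64 × 12 grid at 0.7 × 0.7 × 5 mm spacing — the clinical in-plane
  resolution with a desk-scale matrix, chosen so a full 14-subject cohort
  extracts in under a minute;
* an ellipsoidal GTV (default semi-axes 14 × 14 × 4 voxels, ~3300 voxels);
* a connected GTVr blob grown from an interior seed voxel by
  jittered-distance accretion until 30% of the GTV volume, which
  guarantees GTVr ⊂ GTV and connectedness;
* per-habitat textures from Gaussian random fields: white noise smoothed
  by a Gaussian kernel with the habitat's correlation length (FFT circular
  convolution), rescaled to a common marginal SD of 80 intensity units;
* a 95%-isodose mask covering a configurable fraction (default 0.97) of
  GTVr, constructed by dilating the tumor ellipsoid and releasing the
  outermost GTVr voxels.

The defaults give the recurrent habitat a *longer* correlation length
(2.5 voxels vs 1.0) plus a +60 intensity shift. A coarser, patchier
texture lowers NGTDM busyness and raises coarseness and strength in the
recurrent habitat, and lowers its within-region intensity variance — the
direction of every headline contrast the paired design is meant to detect.
The effect sizes are free parameters of the generator; the defaults were
chosen once so that a cohort of 14 subjects detects the NGTDM contrasts at
the Bonferroni level with high probability, which the acceptance suite
verifies over 50 seeded cohorts.

What the phantom deliberately does **not** model: MRI bias fields, coil
sensitivity profiles, partial-volume effects at tumor boundaries, lesion
growth, or inter-scanner variability. Passing tests on phantoms therefore
demonstrate that the pipeline's arithmetic and statistics behave as
specified — not that any particular clinical effect size is real or that
features are robust to acquisition differences.

Intensities are clipped to [0, 4095] to emulate scanner dynamic range; at
the defaults the clipping rate is far below 0.1%. Generation is
deterministic given `(seed, subject_index)` — cohorts re-generate
bit-identically, which the test suite checks via file hashes.

## Numerical and degenerate-input policy

* Constant ROI: variance 0; standardized moments are NaN and flagged with
  a reason; GLCM collapses to one cell (energy 1, contrast 0); NGTDM
  deviations are all zero (contrast 0, busyness 0, coarseness 1e6).
* A habitat below 8 voxels flags the subject as unusable; no partial
  feature vector is emitted.
* A GTVr that covers the whole GTV leaves an empty non-recurrent habitat:
  the subject is excluded and listed in the run report, never silently
  dropped.
* GTVr voxels outside the GTV are clipped into the recurrent habitat with
  a warning (the recurrence contour originates on a different scan; small
  excursions are expected, and rejecting them would bias against boundary
  recurrences).
* Zero-variance difference columns are flagged degenerate and never
  declared significant.
* Feature columns are always written in the same canonical order, so
  repeated runs produce diffable CSVs.

## Problem sizes used in the checks

The packaged verification uses: random ROIs up to 6 × 6 × 4 voxels against
brute-force oracles (50+ per family); 1000 null cohorts for the type-I
calibration; 50 seeded phantom cohorts of 14 subjects for the
effect-recovery study; and 1000-draw samples for the quantizer's analytic
uniform check. These sizes make the full suite run in minutes while
keeping every Monte-Carlo margin wide relative to its binomial noise.

## Worked example

```{r example, eval = FALSE}
library(hetrad)

run <- run_pipeline(
  list(phantom = list(n_subjects = 14), seed = 7),
  out_dir = tempfile("hetrad_run_")
)

glance(run$study)          # cohort summary: counts, threshold, PC1/PC2
tidy(run$study) |>         # per-feature paired tests
  filter(significant) |>
  arrange(p_value)
autoplot(run$study, "pca") # PC1/PC2 scatter of the 28 region vectors
```

## Known limitations

* Feature definitions follow one established lineage
  (Galloway/Thibault/Amadasun–King with 13-direction 3D aggregation);
  other published variants normalize run/zone statistics differently, so
  absolute magnitudes are comparable only within a consistent toolchain.
* No isotropic resampling: anisotropic voxels weight through-plane
  neighbors the same as in-plane ones.
* The Wilcoxon branch with heavy ties falls back to a normal
  approximation; at n = 14 this is standard but approximate.
* The phantom's Gaussian-field texture moves first-order, zone and NGTDM
  statistics controllably, but it cannot emulate arbitrary real-tissue
  texture families.
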