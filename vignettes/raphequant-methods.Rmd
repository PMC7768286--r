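---
title: "Methods: semi-automated FISH puncta quantification and innervation density"
author: "raphequant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-automated FISH puncta quantification and innervation density}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raphequant)
```

## What this package computes

Single-molecule FISH (RNAscope) renders each mRNA as a diffraction-limited
punctum; transcript abundance per cell is estimated by counting puncta
inside segmented cell regions. `raphequant` implements the full
semi-automated chain used for this kind of quantification in brain tissue
sections, plus the percent-area measure of axonal bouton innervation used
for projection mapping, and the group-comparison statistics applied to the
resulting per-animal values.

The pipeline stages are:

1. **Nucleus segmentation** from the DAPI channel (`segmentNuclei()`).
2. **Puncta detection** per probe channel (`detectPuncta()`).
3. **Per-cell counting and scoring** (`countPunctaPerCell()`,
   `percentPositive()`, `perAnimalAggregate()`).
4. **Calibration** of detector settings against hand counts
   (`regressionMetrics()`, `gridSearchSettings()`).
5. **Innervation density** and cross-region covariance
   (`percentAreaStack()`, `correlationMatrix()`).
6. **Statistics** (`tFromSummary()`, `tFromSamples()`, `mannWhitneyU()`,
   `oneWayAnova()`).

Everything is exercised end to end on synthetic scenes with exact ground
truth (`makeFishScene()`, `makeInnervationStack()`, `makeRegionCohort()`).

## Segmentation model and conventions

`segmentNuclei()` follows the classic primary-object identification recipe:
a Gaussian preprocessing blur, a light additional smoothing, a global
threshold by minimum cross-entropy (Li's criterion), intensity-based
declumping of touching objects, per-object hole filling, and gating by
equivalent diameter (30--100 px by default) and border contact.

Choices the recipe leaves open, and how this package resolves them:

* **Blur "diameter" to sigma.** The stated preprocessing blur diameter
  (default 18 px) is treated as $2\sigma$, so the default applies
  $\sigma = 9$. An alternative reading ($\sigma$ = diameter) exists; the
  parameter is plain and can be set to either convention.
* **Threshold smoothing scale.** The scale $s$ is applied as a Gaussian
  with $\sigma = s / 1.3488$, so the conventional value 1.3488 means
  $\sigma = 1$ before thresholding.
* **Li threshold.** The global threshold minimises
  $\eta(t) = \sum_{g \le t} g\,h(g)\log(g/\mu_b) + \sum_{g > t} g\,h(g)\log(g/\mu_f)$
  over every candidate cut of the intensity histogram; the implementation
  evaluates all cuts with cumulative sums, which is exact — the test suite
  checks it against independent exhaustive minimisation of the full
  criterion. Foreground is strictly above the returned threshold.
* **Declumping "based on intensity".** Seeds are local maxima of the
  preprocessed intensity inside the mask with a minimum separation of half
  the minimum diameter; objects are then grown by a seeded priority-flood
  watershed on the inverted preprocessed intensity restricted to the mask,
  with 4-connected growth. Every binary component is guaranteed at least
  one seed (its intensity argmax).
* **Connectivity.** Objects are 4-connected; background holes are
  8-connected. A hole bordered by more than one object is left unfilled.
* **Order of gates.** Declumping precedes hole filling; size and border
  gates come last. Whether border exclusion preceded declumping in the
  original protocol is unstated; here it follows.

## Spot detection

`detectPuncta()` chains rolling-ball background subtraction, a
difference-of-Gaussian (DoG) band-pass, and topographic-prominence maxima:

* **Rolling ball.** The background is the grayscale opening of the image
  with a ball-shaped (spherical-cap height) structuring element of radius
  50 px by default, computed directly as erosion followed by dilation with
  the non-flat element -- no down-scaling shortcut -- and subtracted with
  clamping at zero. A paraboloid element is available as an option.
* **DoG.** `blur(s1) - blur(s2)` with $0 < s_1 < s_2$; bright puncta map
  to positive responses and the signed image is passed to maxima finding
  without clamping. Blurs use reflective boundaries and kernels truncated
  at $4\sigma$.
* **Prominence maxima.** A local maximum is kept when its topographic
  prominence -- height minus the highest saddle connecting it to
  dominating terrain -- reaches the per-probe cutoff. Equal-valued
  plateaus (8-connected) count once, at their centroid rounded to the
  nearest pixel. Ties between equal-height peaks are resolved by an elder
  rule (the plateau whose first pixel comes earliest in column-major order
  dominates), so of two equal twins separated by a shallow saddle exactly
  one is reported. Maxima never dominated (including the global maximum)
  measure prominence from the image minimum; a constant image has no
  maxima. The implementation is a union-find sweep over pixels in
  descending intensity order and is tested for exact set equality against
  a brute-force flood oracle on random 8-bit images.
* **No sub-pixel localisation.** Counting, not localisation, is the
  endpoint; puncta are pixel coordinates.

The per-probe settings table ships in `probeRegistry()` (s1, s2 and
prominence per probe, with the concordance each achieved against hand
counts), and `gridSearchSettings()` reproduces the calibration workflow:
every valid $(s_1, s_2, p)$ combination is scored by OLS of automated
against hand counts, ranked by $R^2$, with ties broken by MAE then RMSE.
RMSE and MAE are computed on raw automated-minus-hand differences by
default -- they then measure absolute count agreement, the biologically
reported quantity -- with OLS-residual errors available via a flag.

## Counting and aggregation

Puncta are assigned by containment: label identity for nucleus maps,
boundary-inclusive even-odd polygon tests for soma outlines. A punctum in
no ROI is dropped (and tallied); a punctum in overlapping outlines is an
error unless a priority order is supplied, so no punctum is ever counted
twice. A cell is "positive" when its count reaches the threshold (default
1 punctum). Animal averages -- never cells pooled across animals -- are
the statistical units, enforced by `perAnimalAggregate()`. Sampled-section
totals use the every-k-th-section estimator (`estimateTotalCells()`,
interval 6 by default).

## Innervation density

`percentAreaStack()` processes each optical slice with rolling-ball
subtraction (radius 25 px default for these smaller fields), a global
threshold, and a minimum particle size (4 px default), then pools:
$100 \times$ occupied pixels / total pixels over all slices. The original
protocol's exact threshold is inherited from an unpublished macro, so a
documented stand-in is used: median $+ k \cdot 1.4826 \cdot$ MAD of the
background-subtracted slice, $k = 3$ by default. The robust location/scale
pair is deliberate -- with up to ~10% of pixels occupied by signal, a
mean/SD estimate is contaminated by the very signal being measured, while
the median/MAD tracks the background; `method = "mean_sd"` is provided for
comparison. Isolated supra-threshold noise pixels are removed by the
particle-size gate rather than by raising $k$.

Cross-region structure uses pairwise Pearson correlation over animals
within a group (`correlationMatrix()`), two-tailed p from
$t = r\sqrt{(n-2)/(1-r^2)}$, complete-case deletion per pair (pairs with
fewer than 3 complete animals are left `NA` with a warning), and a
green/black diverging heatmap (`plotCorrelationMatrix()`). Exact p-values
are reported; significance stars are left to the caller.

## Statistics

The pooled-variance (not Welch) two-sample t test is used throughout
because printed degrees of freedom of the reconstructed comparisons equal
$n_1 + n_2 - 2$. `tFromSummary()` rebuilds the test from printed
mean/SEM/n triples ($SD_i = SEM_i\sqrt{n_i}$, pooled variance, two-tailed
p); `publishedGroupSummaries()` ships the printed triples that are
reconstructable, and the suite checks each against its printed t to
$|\Delta t| \le 0.02$ (the residual reflects rounding of the printed
inputs). Mann-Whitney U reports the smaller of $U_1, U_2$ with midranks;
p is exact (Wilcoxon null distribution) when $n_1 + n_2 \le 16$ without
ties, otherwise a tie- and continuity-corrected normal approximation.
One-way ANOVA delegates to the standard equal-variance decomposition and
satisfies $F = t^2$ for two groups to $10^{-9}$.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated:

* **Nuclei** are anisotropic ellipses (axis ratio 0.85--1, area preserved
  at $\pi r^2$) with radii 27--34 px -- mid-range of the 30--100 px
  diameter gate -- a centre-weighted interior profile (a bright core bump
  of width $0.3r$ on a 0.5-amplitude plateau, with a steep edge roll-off
  beyond the boundary), composed across nuclei by per-pixel maximum so
  touching nuclei keep an intensity dip along the contact line. Touching
  pairs are placed at centre separations of 0.8--1.2 mean radii. A
  nonspecific tissue background (default 20% of nuclear amplitude) is
  added: real sections are never black, and the Li threshold -- which is
  not shift-invariant -- lands unrealistically low without it. The
  interior profile and radius range were fixed once at design time from a
  one-dimensional scale-space analysis: after the default $\sigma = 9$
  preprocessing blur, a pair of centre-weighted nuclei keeps two intensity
  maxima down to separations of about $0.8 r$ only when $r \gtrsim 27$ px,
  which is what makes intensity declumping a fair test rather than an
  impossible one.
* **Puncta** are Gaussian spots ($\sigma = 1.2$ px, amplitude 100) placed
  uniformly inside label regions with a minimum centre separation of
  $4\sigma$ (the contract requires at least $2\sigma$; the default keeps
  neighbouring spots resolvable by the DoG at the study densities of up to
  30 puncta per cell). Diffuse background blobs ($\sigma = 12$, amplitude
  10) and additive Gaussian noise ($\sigma = 5$, i.e. spot SNR 20; SNR is
  defined as spot amplitude over noise sigma) complete the channel.
* **Bouton stacks** stamp hard disks (radius 2 px, amplitude 100 with
  15% per-bouton jitter) into random slices until the pooled occupied
  fraction reaches the target, so truth is exact by construction.
* **Group samples** (`makeGroupSamples()`) are affinely rescaled to the
  requested mean and SEM exactly, enabling round trips between raw-sample
  and summary-statistics tests.
* **Region cohorts** (`makeRegionCohort()`) draw per-animal densities from
  a multivariate normal with a requested correlation matrix, clamped to
  [0, 100].

What the generator does **not** emulate: optical anisotropy and z-blur
(scenes are 2D projections by design), chromatic shift between channels,
nonuniform illumination, autofluorescent debris, Poisson photon statistics
(noise is additive Gaussian; SNR is amplitude over noise sigma), and
nucleus texture beyond the radial gradient. Passing tests therefore show
that the computations are correct and well-calibrated under controlled
conditions -- not that the specific published per-probe settings transfer
to any particular microscope.

## Numerical choices and degenerate inputs

* Coordinates are 0-based pixel indices, `x` = column, `y` = row,
  everywhere.
* Reflective (half-sample symmetric) boundaries for all Gaussian blurs;
  morphological operations ignore out-of-bounds offsets.
* A constant image is an error for thresholding (degenerate histogram),
  yields no maxima, and segments to an all-zero label map; an empty mask
  is a valid all-zero result, not an error.
* Plateau centroids round half-up; watershed ties resolve by insertion
  order, making every output deterministic.
* Scene seeds fix outputs bit-for-bit; every stochastic routine takes an
  explicit seed and restores the caller's RNG state.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run at desk scale: 24x24 8-bit
images for the maxima oracle (200 images, prominences 1--50), 560--700 px
scenes with 14--25 nuclei for segmentation and detection, 21-slice
128x128 stacks for innervation, cohorts of 50 synthetic animals for
correlation recovery, and 2,000 null replicates for type-I calibration.
These sizes were chosen so the whole suite completes in minutes while
keeping every estimate's sampling error well inside the asserted bands.

## Known limitations

* The rolling-ball opening is exact but $O(N \cdot r^2)$; a 640 px image
  at radius 50 takes tens of seconds. Calibration reuses one
  background-subtracted image across the whole settings grid.
* Prominence tie-breaking (elder rule) is a convention; any consistent
  rule yields the same counts except on exactly-equal twin peaks.
* The innervation threshold is a documented stand-in for an unpublished
  macro; absolute percent-area values depend on it, recovery of known
  synthetic fractions is what the tests certify.
* Manual-edit polygons are rasterised with a boundary-inclusive even-odd
  rule; self-intersecting polygons follow that rule literally.
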