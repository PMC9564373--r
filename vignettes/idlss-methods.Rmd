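---
title: "Dose-interval lung subregions for pneumonitis modeling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-interval lung subregions for pneumonitis modeling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Severe (grade >= 2) acute radiation pneumonitis (ARP) is a common toxicity
of thoracic radiotherapy. Classical predictors are whole-lung dose-volume
summaries (V20, mean lung dose), which discard the spatial arrangement of
dose within the lung. `idlss` implements a subregion-based alternative:
the lung is partitioned by *incremental dose intervals* — the intersections
of the whole-lung mask with the contiguous dose bands 0-10, 10-20, 20-30,
30-40 and 40-50 Gy — and image and dose features are computed per
subregion, so that a model can weight the behaviour of, say, the low-dose
lung separately from the high-dose bath. The package provides the entire
chain: volume I/O and alignment, the partition, a self-contained radiomics
engine, dose features, stability feature selection, ridge modeling with
repeated stratified splits, and a synthetic phantom generator that makes
every stage testable without patient data.

## The partition

A lung voxel with dose $D$ is assigned to band $i$ iff
$e_i \le D < e_{i+1}$ for the edge vector $e = (0, 10, 20, 30, 40, 50)$ Gy.
Half-open intervals guarantee disjointness; a dose of exactly 0 Gy falls in
the first band. Lung voxels at or above the last edge (prescriptions run up
to 72 Gy) are excluded from all bands and reported as `excluded_fraction`;
`extend_last = TRUE` folds them into the final band instead. The choice to
exclude rather than merge is a genuine design decision — the interval
scheme itself stops at 50 Gy and says nothing about hotter voxels — and the
excluded fraction is surfaced so the user can see how much lung is
unassigned. Regions below 27 voxels (one 3x3x3 neighbourhood) produce
missing features rather than unstable texture estimates.

## Feature extraction

### Radiomics (per region, 4610 features)

The engine follows IBSI-style definitions with these frozen conventions:

* **Image types (12).** Original; Laplacian-of-Gaussian at sigma = 1, 3
  and 6 mm (sigma interpreted in physical millimetres, converted per axis
  through the voxel spacing; mirror boundaries); the 8 subbands of a
  single-level *undecimated* separable coiflet-1 wavelet transform
  (periodic boundary). The transform is undecimated precisely so that the
  subbands stay on the acquisition grid and the region mask applies
  without resampling.
* **Discretization.** Fixed bin counts 20, 50, 100, 150, 200 over the
  in-region min-max range; a constant region maps to bin 1.
* **Families.** Shape (14, original mask only), first-order (18, once per
  image type; entropy/uniformity use a reference bin count of 50), and the
  five texture families per image type per bin count: GLCM 22, GLRLM 16,
  GLSZM 16, GLDM 14, NGTDM 5 (73 in total). The count decomposes as
  14 + 18 x 12 + 73 x 12 x 5 = 4610 per region and 27,660 over the whole
  lung plus the five subregions. This decomposition is the package's
  reconstruction of the protocol total; every family list is configurable
  through `radiomics_config()`.

Texture conventions: GLCM is symmetric at Chebyshev distance 1 with
feature values averaged over the 13 unique 3D directions (GLRLM likewise);
GLSZM zones are 26-connected components of equal gray level; GLDM uses
dependence threshold 0, with the dependence count including the centre
voxel so that the $1/j^2$ weights never divide by zero; NGTDM uses the
26-neighbourhood mean. Correlation of a degenerate (single-level) GLCM is
defined as 1. All matrix builders are validated against literal
nested-loop enumeration oracles in the test suite.

Shape uses a marching-tetrahedra triangulation of the 0.5 isosurface. The
binary mask is lightly smoothed (Gaussian, 0.6 voxel) before meshing so
edge crossings interpolate the level set instead of snapping to voxel
midpoints — a faceted binary mesh overestimates a sphere's surface by
~15%, which would push sphericity far from 1 for genuinely round objects.
Very small masks, which smoothing would erase, fall back to the raw
binary mesh. Axis lengths come from the inertia tensor of voxel centres
(4 sqrt(eigenvalue)); maximum 3D diameter is the largest distance between
surface voxel centres.

### Dose features (per region, 213 features)

* **Scale-invariant 3D dose moments (63).** Central moments
  $\mu_{pqr} = \sum_v (x_v-\bar x)^p (y_v-\bar y)^q (z_v-\bar z)^r D(v)$
  over the region, coordinates in physical mm about the dose-weighted
  centroid, normalized as $\eta_{pqr} = \mu_{pqr} / \mu_{000}^{(p+q+r)/3 + 1}$
  for all orders 0-3 per axis except (0,0,0), whose value is constant 1.
  The construction is exactly translation invariant, exactly homogeneous
  of degree $-(p+q+r)/3$ in dose amplitude, and invariant to isotropic
  object scaling up to discretization (verified at 3% on a Gaussian-blob
  phantom). Whether the original construction used voxel or physical
  coordinates is not recoverable; physical millimetres are used because
  the moments are geometric quantities.
* **DVH parameters (59).** $V_x$ (strictly "more than x Gy"), relative
  (%) and absolute (cc), for x = 5..80 Gy in steps of 5; $D_x$ (dose to
  the hottest x% of the region, the (100-x)th percentile of voxel doses
  with linear interpolation) for x = 1, 2, 5, 10..95 step 5, 98, 99; and
  mean/median/min/max dose. The 59-member list is the package's frozen
  choice; the protocol total 63 + 59 + 91 = 213 pins down its size but
  not its membership.
* **Dose-map dosiomics (91).** The engine's 18 first-order plus 73
  texture features on the unfiltered dose map, discretized at 50 bins
  (the dose binning is unstated in the source protocol; 50 matches the
  first-order reference bin count).

## Feature selection

`select_features()` implements the five-step stability screen: (1) a
stratified subsample of 70% of patients (class ratio preserved to the
nearest integer — 88 cases of a 64/62 cohort of 126); (2) removal of
zero-variance features; (3) z-scoring and a two-sided Welch t-test
against the outcome, keeping features with p <= 0.1 (the t statistic is
invariant to the affine z-scoring, which is nevertheless applied as
stated); (4) after 100 seeded iterations, retention of the
max(10% of the feature count, 10) most frequently surviving features,
ties broken by larger mean |t| and then lexicographically; (5) Pearson
redundancy pruning: pairs with |R| > 0.5 are processed in descending |R|,
and from each still-active pair the member with the higher mean absolute
correlation to the other candidates (computed once up front) is removed.
Welch rather than the equal-variance variant is the safer default where
the test variant is unstated. Everything is deterministic given the seed
vector (iteration i uses seed i).

One genuinely open point is whether selection saw only training data or
the full dataset. The package defaults to leak-free behaviour — selection
runs inside each evaluation split on the training part only — and exposes
`selection_mode = "global"` for the literal single-pass reading. A canary
test (a feature equal to the test labels must not lift test AUC) guards
the default mode.

The suite also calibrates the screen against a permutation null. Because
the 100 screening iterations subsample the *same* dataset, retention
events for a fixed label permutation are strongly correlated — a chance
full-data association keeps one feature alive in most iterations, so a
binomial bound on frequencies would be wrong. The calibration therefore
re-permutes the labels independently in every iteration, which makes
retention events independent Bernoulli draws at the t-test level and the
Bonferroni-corrected binomial bound exact.

## Modeling and evaluation

"Ridge" for a binary endpoint is implemented as L2-penalized least squares
on {0,1} labels (glmnet, alpha = 0), with the continuous prediction as
the ranking score and 0.5 as the classification threshold; the penalty is
chosen from a 13-point log grid (1e-3..1e3) by stratified 5-fold CV
maximizing the mean AUC of the continuous prediction, ties preferring the
stronger penalty. Evaluation uses stratified 70/30 splits
(round(0.7 x class size) per class), 30 splits by default (seeds
`seed_base + 0..29`), reporting AUC (rank-based, ties averaged),
accuracy, precision (0 when no positive predictions), recall and F1 per
cohort, with means and STDs recomputable from the per-split records.
Model comparison is a two-sided two-sample Student's t-test on the
per-split test AUCs (p = 1 for identical constant vectors); an unpaired
test matches the stated method even though splits are shared, and the
choice is recorded here because a paired test would be more powerful.

The six canonical feature groups are WL-RF, WL-DF, WL-RDF (whole-lung
columns only) and SR-RF, SR-DF, SR-RDF (the five subregion blocks only,
whole lung excluded). Whether the original subregion groups also included
whole-lung columns is unstated; excluding them keeps the contrast clean.

## The synthetic phantom and cohort

`make_phantom()` builds a two-lobed ellipsoidal lung in a 40^3 grid at
3 mm isotropic spacing (a deliberately small, desk-scale thorax), a
spherical tumour focus receiving the 60 Gy prescription with an isotropic
Gaussian falloff (scale 15 mm, chosen once so that every 0-50 Gy band
holds several hundred lung voxels and ~14% of lung exceeds 50 Gy,
comparable to a conformal stage-III plan), and lung CT texture as a
correlated Gaussian field (SD 60 HU, correlation length 6 mm) around
-800 HU.

The planted outcome signal mirrors the qualitative driver the subregion
approach is meant to exploit: *inter-patient variation in the spatial
heterogeneity pattern of the low-dose lung*. Each patient receives a
correlated dose-heterogeneity field below 20 Gy whose marginal amplitude
is fixed at 0.4 Gy but whose correlation length varies across patients;
the outcome follows a logistic model on the standardized log correlation
length (coefficient 2.5) plus a weaker CT-texture term (0.5) and a small
noise term, with the intercept solved for the target 50% event rate. The
amplitude is the load-bearing choice: 0.4 Gy is a third of the
whole-lung discretization width (60 Gy / 50 bins), so whole-lung dose
textures largely quantize the pattern away, while the 0-10 Gy subregion
(bin width 0.2 Gy) resolves it — exactly the dilution argument for
subregion features, expressed at the scale of the discretizer rather
than as an arbitrary label assignment. Because the marginal amplitude is
fixed, whole-lung DVH parameters and moments carry essentially no
signal.

What the phantom does *not* emulate: anatomical lobes and airways,
heterogeneous body outline, scanner-specific CT noise, deformable
anatomy, or Monte-Carlo dose physics. Passing tests therefore demonstrate
correctness of the machinery and the *direction* of the
subregion-vs-whole-lung contrast under a controlled generative model —
not clinical performance on real cohorts.

## Problem sizes in the test suite

The suite exercises the same code paths as a full run at sizes chosen for
a desk machine: oracle comparisons on <= 5^3 regions; full 4610-feature
extraction on one phantom subregion; the directional subregion-vs-whole-
lung experiment on 10 replicate cohorts of n = 80 patients with the dose
feature groups, 10 splits and 30 screening iterations per selection (the
phantom defaults themselves are the study conditions; only the replicate
count, cohort size and iteration counts are reduced). The acceptance
script recomputes the headline bookkeeping — eta_000 = 1, 4610 features
per region, 27,660 columns over six regions — on the default phantom with
full per-region extraction.

## Known limitations

* The 4610/213 decompositions are reconstructions consistent with the
  protocol totals, not a published itemization; both are configurable.
* The redundancy-pruning heuristic removes the most *central* member of a
  correlated pair, which can discard the individually strongest feature
  of a correlated informative cluster; it is implemented as stated rather
  than improved, and the repeated-split averaging absorbs the resulting
  variance.
* NRRD support covers attached-data, axis-aligned files (raw or gzip) —
  the subset the pipeline itself writes.
* Feature reproducibility under perturbation (rescan, re-contour) is out
  of scope.
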