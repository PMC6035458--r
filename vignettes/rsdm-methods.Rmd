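---
title: "Rectum surface dose maps and toxicity prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rectum surface dose maps and toxicity prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Locally advanced cervical cancer is commonly treated with external beam
radiotherapy (EBRT) followed by an intracavitary brachytherapy (BT) boost.
The rectum sits immediately posterior to the applicator and receives a
steep, anterior-weighted dose gradient in every BT fraction; late rectal
toxicity (bleeding, mucosal injury) limits dose escalation. Conventional
monitoring uses dose-volume parameters such as D0.1cc/D1cc/D2cc — the
minimum dose in the most exposed 0.1/1/2 cm^3 of rectal wall — which
discard all spatial information and are usually accumulated under a
*static-hotspot assumption* (SA): fractional doses are summed as if the hot
region sat on the same piece of tissue every fraction, which inter-fraction
rectal deformation routinely violates.

`rsdmtox` implements a spatially explicit alternative as a reusable
toolkit:

1. **Deformable accumulation.** Each BT fraction's rectal surface is
   registered non-rigidly onto the first fraction's surface; fractional
   surface doses are converted to EQD2 and summed on the reference surface.
   The homogeneous EBRT phase is added as a scalar.
2. **Flattening.** The cumulative 3D surface dose is unrolled into a 2D
   rectum surface dose map (RSDM) that preserves physical length along both
   the superior-inferior and circumferential directions.
3. **Feature extraction.** 21 dose-volume parameters (DVPs) from the 3D
   dose, 43 gray-level texture features and 224 dose-geometric parameters
   (DGPs) from the RSDM.
4. **Prediction.** After screening (PCA or Mann-Whitney U), a
   SMOTE-balanced RBF-SVM with sequential forward feature selection (SFS)
   is evaluated by repeated stratified 5-fold cross-validation, reporting
   ACC/SEN/SPE/AUC and per-feature selection frequencies.

A deterministic synthetic-cohort generator reproduces the statistical and
geometric structure the pipeline assumes, so every stage — and the
end-to-end prediction — is testable without patient data.

## Dose model

Physical dose is converted to the equieffective dose in 2 Gy fractions
under the linear-quadratic model,

$$\mathrm{EQD2} = D\,\frac{d + \alpha/\beta}{2 + \alpha/\beta},$$

with `alpha_beta = 3` Gy for rectum (late-responding tissue). BT surface
dose is strongly heterogeneous, so the conversion of a single delivered
fraction uses the *vertex's own* fractional dose as the fraction size
(`D = d =` local dose); the prescription value would understate the
biological weight of hotspots and overstate cold regions. This choice is a
configuration-visible assumption: the LQ model is applied to the fraction
size actually received locally. The EBRT phase (45 Gy in 25 fractions of
1.8 Gy, EQD2 43.2 Gy) is assumed homogeneous over the pelvis and added as a
scalar without deformation; EBRT-to-BT deformable registration is
deliberately out of scope because the applicator destroys point
correspondence between the two anatomies.

## Registration

The module exposes a registration *interface* — `register(moving, fixed,
params) -> DVF` — with a default implementation based on coherent
Gaussian-mixture point matching: moving vertices act as GMM centroids fitted
to the fixed cloud by EM, with displacements constrained to a smooth
Gaussian reproducing-kernel field (motion coherence, kernel width `beta`,
weight `lambda`) and a uniform outlier component (`outlier_w = 0.1`). Two
practical details matter:

* **Rigid pre-alignment and symmetric subsampling.** Centroids are matched
  first, and when clouds exceed `max_control` points both are subsampled by
  the same regular pattern; the fitted displacement field is interpolated
  back to all vertices through the same kernel. An asymmetric design
  (subsampled centroids against a denser target) systematically biases
  centroids off the surface.
* **Local-topology penalty.** A short Laplacian smoothing pass of the
  displacement field over the mesh adjacency graph discourages
  neighbourhood fold-over, standing in for the energy term of
  topology-preserving point-matching algorithms whose internals are not
  part of this package's contract.

Quality is quantified by four metrics: Dice coefficient (DC) and percent
error (PE) on voxelised enclosed volumes (1 mm isotropic by default;
slab-wise polygon interpolation caps the open tube implicitly), and mean
vertex-to-vertex (VVD) plus Hausdorff (HD) distances on nearest vertices.
PE is defined as the symmetric-difference volume over the reference volume
— the quantity is only named, not defined, in the sources this design
follows, so the definition is isolated in one function. VVD/PE are
directional (first argument = moving); DC/HD are symmetric.

## Flattening and its one deliberate deviation

Each slice contour is cut at its posterior-most point and unrolled
counter-clockwise (viewed from superior) by arc length into one row; dose is
interpolated linearly along the contour at `col_spacing` (1 mm) columns.
Rows are left-aligned at the cut and the ragged right edge is masked, so map
width is patient-specific — no inter-patient resampling is performed, which
keeps geometric features in physical units.

With rows at slice planes and constant pixel height, the map area would
equal `ns/(ns-1)` times the tube's trapezoidal lateral area (3-4% at
clinical slice counts), breaking area conservation between the 3D surface
and the map. The package therefore assigns the two boundary rows
half-height pixels (`row_height` field): `rsdm_area()` then integrates to
exactly the trapezoidal mesh area while per-row circumference still equals
the contour perimeter. Manually constructed maps default to constant row
heights, so the simple `count x spacing` arithmetic still holds for toy
grids.

## Features

* **DVPs.** Vertices are sorted by dose descending and cumulative volume is
  accumulated as `area x wall_thickness` (default 3 mm). `Dx` is the dose
  at which cumulative volume reaches `x` for the 21 volumes 0.1 and 0.5-10
  cm^3 in 0.5 steps. The area-to-volume rule is the package's largest
  modelling assumption and is isolated in one parameter.
* **Textures (43).** Three first-order statistics (mean, SD, skewness) on
  raw dose, plus matrix features on a 32-level range-relative quantization:
  9 GLCM (energy, contrast, correlation, homogeneity, entropy, variance,
  sum-average, dissimilarity, autocorrelation; symmetric, distance 1, four
  directions averaged), 13 GLRLM (the canonical SRE...RLV set; runs broken
  by the mask), 13 GLSZM (zone analogues with 8-connected zones, including
  LGZE/HGZE/SZHGE), and 5 NGTDM (coarseness, contrast, busyness,
  complexity, strength). Because quantization is range-relative, all matrix
  features are invariant to a constant dose offset; only the first-order
  mean shifts. The exact 43-name list and quantization depth are package
  choices (the counts, not the names, are externally fixed); tests pin the
  implementation against brute-force matrix-construction oracles rather
  than against any published value.
* **DGPs (224).** For each dose level t in 45..100 Gy the region is the set
  of valid pixels with dose >= t; four descriptors are emitted: relative
  area (%), marching-squares perimeter (mm), relative width (%: maximal
  per-row arc length over that row's circumference, wrap-aware across the
  cut), and length (mm: rows intersecting the region times row spacing, so
  disjoint islands do not inflate it). The marching-squares estimator
  measures the digitised region's boundary; on coarse digitised disks it
  overestimates the ideal circle's perimeter (about 14% at r = 5 px,
  inside 10% from r = 8 px) — a property of digitisation, not a defect, and
  irrelevant to monotone-trend uses of the feature.

## Screening and prediction

`pca_features()` z-scores features (constant columns dropped), then keeps
the smallest number of principal components explaining more than 99% of
variance; standardisation is the defensible default because features mix
Gy, %, mm and unitless scales. `mwu_screen()` performs per-feature
two-sided Mann-Whitney U tests, exact when both groups are <= 10 and
tie-free, otherwise a tie- and continuity-corrected normal approximation;
raw p-values are the default (the screening is exploratory), with
Bonferroni/BH available behind a flag.

The classifier is an RBF-kernel C-SVC (C = 1, gamma = 1/p on z-scored
features) trained by a deterministic SMO solver implemented in C++ — no
SVM library ships in the supported runtime, and determinism (fixed
iteration order, no random heuristics) is required for reproducible
pipelines. SMOTE balances only the *training* portion of each fold —
validation instances are never oversampled or synthesised — generating
synthetic minority samples uniformly along segments to one of the k = 5
nearest minority neighbours. SFS greedily adds the feature maximising the
inner 5-fold CV AUC, stopping when the improvement drops below 1e-4 or at
`sfs_max` (default 10) features; ties break to the lower feature index.
Repeated (default 100 x) stratified 5-fold CV reports mean ACC/SEN/SPE (at
decision threshold 0, pooled per repeat), per-repeat AUC from pooled fold
scores (the per-repeat-pooled choice is one of two defensible readings and
is fixed here), an empirical 2.5/97.5-percentile AUC CI over repeats, and
selection frequencies over all repeats x folds. ROC curves are compared by
the paired DeLong placement Z-test with Bonferroni adjustment.

## The synthetic cohort: what it emulates, and what a green test means

`generate_cohort()` draws, per patient: a tube of elliptical cross-sections
(semi-axes ~11-16 x 8-13 mm) with low-order harmonic irregularity and a
smooth centerline wobble (`shape_amplitude`, 3 mm), length uniform in 60-90
mm at 2.5 mm slice spacing; per-fraction smooth in-plane deformations (sum
of six Gaussian bumps, rescaled so the maximum displacement equals
`deformation_amplitude`, 4 mm — the scale of reported pre-registration
vertex distances); and a BT point source placed `source_standoff` (9 mm,
jittered per patient and fraction) anterior of the local anterior wall with
an inverse-square field normalised to the prescription fraction dose at
`hotspot_r0` = 10 mm and capped at 3x strength. Schemes alternate 4 x 7 Gy
and 5 x 6 Gy; EBRT is always 45 Gy / 25 x 1.8 Gy. These defaults produce
anterior-wall doses on the prescription scale and high-dose (>= 65 Gy EQD2)
relative areas spanning roughly 0-25%, the magnitude reported for real
cohorts.

Labels are drawn from `logistic(alpha + slope * area>=65Gy)` with `alpha`
calibrated by root-finding so the expected prevalence matches the spec
(default 12/42); `effect_family = "null"` zeroes the slope for
type-I-error checks. The generator stores true correspondences, so
accumulation with injected true DVFs must reproduce the analytic ground
truth to machine precision — the accumulation oracle.

Deliberate non-realisms: deformations are in-plane only (a planar contour
stack cannot represent out-of-plane warp), dosimetry is a capped point
source rather than an applicator model, and no clinical covariates exist.
A green end-to-end test therefore establishes that the pipeline recovers a
*planted, dose-geometry-mediated* effect and stays at chance under the
null — not that any particular clinical effect size is reproduced.
Published cohort-level results derive from patient data that are not
available; they are explicitly not reproduction targets, and no numeric
acceptance targets are defined for this package.

## Numerical choices and degenerate inputs

* Contours are normalised CCW-from-superior with the start vertex rotated
  to the posterior-most point; duplicated closing vertices are dropped;
  self-intersecting polygons are rejected at load (the deformation
  generator retries with damped amplitude if it ever produces one).
* Constant maps quantize to a single level; GLCM correlation of a
  single-level map is defined as 0; NGTDM uses an epsilon of 1e-12 in
  coarseness/strength denominators.
* Dx for volumes beyond the total wall volume returns the minimum dose and
  is flagged (`truncated` attribute) with a warning.
* Dose sampling outside the grid clamps to the boundary with a warning.
* Zero-denominator confusion metrics return NA with a warning rather than
  failing a whole CV run.
* All randomness flows through explicit seeds: a master seed spawns
  per-patient, per-fraction, per-repeat, per-fold and SMOTE sub-seeds via a
  deterministic integer recurrence kept below 2^31, and every seeded
  operation restores the caller's RNG state.

## Known limitations

* The default registration is a generic coherent point matcher; it honours
  the interface contract (smooth, topology-respecting DVFs that improve all
  four metrics on the test suite's deformations) but is not a numerical
  reproduction of any specific published algorithm.
* DVP volumes depend linearly on the nominal wall thickness; only the
  default (3 mm) is exercised by tests.
* The flattening dialect (posterior cut, CCW, left-aligned) is one of
  several length-preserving conventions; texture features are sensitive to
  the alignment choice, which is why tests pin oracle equivalence rather
  than specific texture values.
* Small-cohort CV results are noisy; the null-cohort AUC band [0.4, 0.6]
  and the planted-effect AUC > 0.75 are properties of the stated synthetic
  world at n = 40, not clinical claims.
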