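---
title: "Multi-lesion PET radiomics with petrad: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-lesion PET radiomics with petrad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petrad)
```

## The problem

Diffuse large B-cell lymphoma (DLBCL) is usually multifocal: a baseline
FDG-PET scan shows anywhere from one to dozens of avid lesions spread over
nodal and extranodal sites. Radiomics pipelines built for solid tumors
quantify a single primary lesion, so for lymphoma one must first decide
*which* lesion — or which combination of lesions — to featurize before
asking whether image features predict progression. `petrad` implements the
full comparison machinery for that question: lesion delineation, an
IBSI-aligned feature engine, patient-level dissemination features, twelve
lesion/feature-selection model variants, and a repeated cross-validated
model-comparison harness with fold-wise DeLong testing.

Because the clinical scans motivating this design are not publicly
deposited, the package also ships a synthetic-data generator that emulates
the relevant statistical structure of such a cohort — multi-lesion patients
with a minority binary endpoint linked to tumor burden, uptake and spread —
with known ground truth, so every stage of the pipeline can be validated
end to end.

## Synthetic cohorts

`phantom_config()` describes one patient image: a grid of standardized
uptake values (SUV) with soft-tissue background (mean SUV 1.0, truncated
Gaussian noise, SD 0.1 SUV) and 1–20 lesions per patient. Lesions are
rendered as a uniform core at the lesion's peak SUV with a 1-voxel Gaussian
rim — a deliberate caricature of partial-volume blur that gives
non-degenerate intensity and texture statistics. Defaults correspond to
core volumes of 1–500 mL (radii drawn log-uniformly, giving the
right-skewed volume distribution typical of lymphoma) and peak SUV 4.5–40
(log-uniform). A consequence of the rim is that the super-threshold (SUV ≥
4.0) volume of a lesion exceeds its core volume by a peak-dependent shell;
the generator therefore records both, and "true MTV" always refers to the
rendered super-threshold volume. Lesion placement enforces disjointness of
the super-threshold supports, so the delineated component count equals the
generated lesion count.

`cohort_config()` adds the outcome model. Each patient's binary endpoint
(progression within two years; a `pfs` label is available for
sensitivity-style analyses, with identical mechanics) is drawn from a
logistic link on three standardized ground-truth summaries: log MTV, peak
SUV, and the maximum distance from the largest (bulk) lesion to any other
lesion (`Dmax_bulk`). Standardization constants and the intercept come from
a 10,000-draw pilot simulation of the ground-truth feature distribution;
the intercept is solved by root finding so that expected prevalence matches
the target (default 52/296 ≈ 17.6%, the imbalance typical of 2-year
progression in treated DLBCL). The pilot sampler ignores the rare placement
rejections of the voxel renderer — a second-order approximation that is
shared consistently by the calibration and by `bayes_auc()`, the
Monte-Carlo estimate of the AUC an oracle using the true linear predictor
would achieve. Default link coefficients are (0.8, 0.3, 0.5) on the
standardized features — tumor burden and spread dominant, uptake secondary,
matching the relative importance this field repeatedly reports; tests that
require a specific oracle difficulty scale this vector (e.g. 1.3× for a
Bayes AUC of 0.80 in the recovery analysis).

What the generator does **not** emulate: anatomy, attenuation, scanner
point-spread functions, reconstruction artifacts, inter-scanner
calibration, or correlated lesion geometry. Passing tests on these
phantoms therefore validate the *computational* pipeline — segmentation
arithmetic, feature definitions, resampling, model evaluation — not the
clinical transferability of any particular feature.

## Delineation and mask editing

`delineate()` implements fixed-threshold preselection: 26-connected
components of voxels with SUV ≥ 4.0 are kept when their volume reaches
3 mL. Both cut-offs are closed bounds and exposed as arguments. Labels are
assigned in decreasing volume order with centroid-lexicographic
tie-breaks, so "lesion 1" is deterministically the largest.
`add_lesion()` emulates the click-to-add step used for small lymphoma
lesions (< 3 mL): the above-threshold component containing a seed voxel is
added regardless of volume. `remove_region()` deletes a labelled region.
`check_scan_quality()` encodes the scan-acceptance rule (hepatic SUV
1.3–3.0 and glucose < 11 mmol/L, rescued by 50–80% of injected activity in
the image); on synthetic data it is advisory metadata and always passes by
construction.

## Feature engine

Every VOI is processed the same way: the five conventional PET features
(MTV, SUVmax, SUVpeak, SUVmean, TLG) are computed on the original grid;
everything else is computed after cropping a padded neighbourhood,
resampling to 2 × 2 × 2 mm with centered-grid trilinear interpolation
(masks interpolated trilinearly and thresholded at 0.5), and fixed-bin
discretization at 0.25 SUV anchored at SUV 0 — a common anchor keeps grey
levels comparable across lesions and patients. SUVpeak uses a 1-mL sphere
of voxel centers positioned at every in-VOI voxel; the sphere may extend
outside the VOI but not outside the image.

The panel cardinalities are pinned to 22 morphology + 50 intensity + 408
texture features (485 with the conventional five):

* **Morphology (22).** Mesh volume and surface area, surface-to-volume
  ratio, compactness 1 and 2, spherical disproportion, sphericity,
  asphericity, centre-of-mass shift, maximum 3D diameter, principal-axis
  lengths, elongation, flatness, and volume/area densities relative to the
  axis-aligned bounding box, the approximate enclosing ellipsoid and the
  convex hull. The isosurface is extracted by marching tetrahedra with
  linear interpolation after smoothing the binary mask with a 0.7-voxel
  Gaussian: meshing the raw binary mask produces a voxel staircase whose
  area overestimates smooth shapes by 10–30% (a digital r = 10 mm sphere
  then scores sphericity ≈ 0.91 instead of ≈ 0.99). Ellipsoid surface area
  uses Thomsen's approximation (max error ≈ 1%); the convex hull is an
  own quickhull over a directional-extreme subset of mesh vertices. Masks
  too small for the smoothed field to reach the iso-level fall back to the
  binary mesh (flagged by a zero smoothing sigma in the mesh record).
* **Intensity (50).** Two local-intensity features (local and global
  intensity peak on the resampled grid), 18 first-order statistics
  (population moments), 23 histogram features on the discretized levels
  (including the histogram-gradient features), and 7 intensity-volume
  histogram features computed on the continuous SUVs with the empirical
  distribution (constant regions pin V ≡ 1 and I10 = I90).
* **Texture (408).** Six grey-level matrix families with IBSI-style
  formulas: GLCM (25 features) and GLRLM (16) under six aggregation
  methods (2D averaged, 2D slice-merged, 2.5D direction-merged, 2.5D
  merged, 3D averaged, 3D merged); GLSZM, GLDZM (16 each), NGTDM (5) and
  NGLDM (17) under 2D / 2.5D / 3D. GLCM distance is 1 in the Chebyshev
  norm (13 unique 3D directions, 4 in-plane); zones are 26-connected in 3D
  and 8-connected in-plane; the distance-zone map uses city-block distance
  to the VOI border (border voxel = 1, in-plane for the 2D variants);
  NGLDM uses coarseness α = 0 with the dependence-count axis stored as
  k + 1. Run/zone percentages divide by the voxel count times the number
  of merged directions. Single-level and single-voxel regions evaluate to
  analytic limits (e.g. GLCM joint entropy 0, correlation pinned to 1)
  rather than `NaN`; the test suite enforces a never-NaN contract over
  random degenerate masks.

The exact membership of the morphology and intensity panels follows the
IBSI feature families, dropping the oriented-bounding-box and
minimum-volume-ellipsoid densities and the intensity-weighted moment
features so that the printed counts (22/50) are met while retaining all
features the comparison study singles out (elongation, spherical
disproportion, compactness, area/volume densities, minimum intensity,
minimum histogram gradient).

At the patient level all lesions are processed as one VOI: the union mask
may be disconnected, its mesh has several shells whose areas add, and its
principal axes are those of the pooled voxel cloud.

## Dissemination features

Eighteen patient-level features: the lesion count; four distance features
(`Dmax_bulk`, `Dmax_patient`, `Dmean_bulk`, `Dmean_patient`) computed
between lesion centroids (the mean of voxel center positions) in
millimetres; five spread statistics (range, SD, coefficient of variation,
max/min ratio, IQR) for each of per-lesion SUVpeak and per-lesion SUVmean;
and three volume-spread features (range, SD, bulk volume fraction =
largest lesion volume / MTV). The bulk lesion is the largest by volume
with the segmentation label order breaking ties. Single-lesion patients
take pinned degenerate values (distances and spreads 0, ratios and the
bulk fraction 1) so feature tables never need imputation. Centroid-based
distances were chosen over surface distances as deterministic, cheap and
rotation-invariant; no normalization by body size is applied.

## The twelve model variants

`build_feature_table()` assembles one patients × features table per
approach: a three-feature reference model (MTV, patient-level SUVpeak,
`Dmax_bulk`); five lesion-selection variants (largest lesion, hottest
lesion, patient-level VOI, and elementwise maximum / median over all
lesions, each 480 radiomics + 5 conventional columns); the dissemination
model (18 + 5); and dissemination combined with each radiomics source
(498 + 5). The maximum/median aggregation applies to the 480 radiomics
features only; the five conventional features are always the
patient-level ones. The reference model's SUVpeak is the patient-level VOI
SUVpeak. Column counts (3 / 485 / 23 / 503) are asserted on every
construction. `lesion_concordance()` reports the fraction of patients
whose largest and hottest lesion coincide, with mismatches broken down by
the largest lesion's volume (< 10 mL) and SUVpeak (< 10).

## Modeling and evaluation

`run_repeated_cv()` wraps outcome-stratified k-fold cross-validation
(default 5 folds, 50 repeats). All data-dependent decisions are fitted on
the training 80% of each fold and applied unchanged to the held-out 20%:

1. natural-log transform of strictly positive columns with sample skewness
   above 0.5 (unseen non-positive values are clipped to half the smallest
   training value);
2. z-scoring;
3. optional SMOTE oversampling of the minority class to 1:1 (synthetic
   rows are convex combinations of a minority row and one of its five
   minority nearest neighbours);
4. optional feature reduction: PCA (components explaining 95% of training
   variance), factor analysis (principal-axis factoring with iterated
   communalities — maximum-likelihood `factanal` is not usable at
   p ≫ n — with the PCA-matched component count), recursive feature
   elimination dropping 10% of features per iteration down to 10 (ranked
   by random-forest impurity importance, linear-SVM weights, or
   ridge-logistic coefficient magnitudes), or univariate ANOVA-F selection
   of the top 10th percentile;
5. ridge-penalized logistic regression with fixed unit penalty strength
   in the mean-log-likelihood convention (glmnet λ = 1/n_train, the
   equivalent of the scikit-learn default `C = 1`); the penalty is
   exposed as an argument.

The mean and SD of the CV-AUC are taken over all repeat × fold test AUCs.
`compare_models()` evaluates two approaches on *shared* fold assignments,
applies the DeLong test to the paired test-fold predictions of every fold,
and reports the median of all fold p values (pinned to all
repeats × folds). Degenerate folds where the paired DeLong variance is
inestimable (a single positive) contribute p = 1. Feature importance is a
random forest (500 trees) on the features surviving the model's reduction method,
with impurity importances normalized to sum to one; PCA-reduced models
are rejected because components are not interpretable features.

Seeds follow a pinned counter scheme (`derive_seed()`): one master seed
deterministically yields per-patient, per-repeat and per-fold seeds, so
every result object is exactly reproducible.

A note on null calibration: with permuted labels the pooled out-of-fold
predictions form a single Mann-Whitney statistic on the event count
(~26-37 events at n = 150), whose null SD is ≈ 0.055 — repeats of the CV
do not shrink it, because every repeat reuses the same patients and the
same permutation. The package's calibration check therefore averages the
CV-AUC over 20 random permutations (the standard permutation-null
estimate), which concentrates the mean at 0.5 ± 0.015; a
single-permutation CV-AUC should be expected to deviate by ±0.1 on
cohorts of this size no matter the classifier.

## Numerical and degenerate-input choices

* Discretized level of an in-mask voxel: `floor((x − anchor)/0.25) + 1`,
  clamped at 1.
* Resampling extrapolates by nearest edge voxel; a mask that vanishes
  under the 0.5 threshold keeps its centroid voxel.
* Texture matrices with no counts (e.g. single-voxel slices) are skipped
  in averaging aggregations; if all are empty the feature set is evaluated
  on a point-mass matrix at the region's level.
* NGTDM coarseness is capped at 10^6; busyness and strength return 0 when
  their denominators vanish.
* DeLong: zero variance with zero AUC difference gives p = 1; inestimable
  variance gives p = 1; zero variance with a non-zero difference gives
  p = 0.
* AUC uses midranks (ties get half credit).

## Problem sizes used in the tests

The shipped test-suite and acceptance analyses run on deliberately scaled
phantoms chosen to exercise every code path at interactive speeds: 40–56
voxel grids at 2 mm, 1–4 lesions of 5–20 mm radius, cohorts of 148–300
patients, and 5-fold × 10–20-repeat cross-validation. The calibration,
recovery and comparison analyses are statistically identical at larger
sizes; only Monte-Carlo noise shrinks.

## Known limitations

* The pinned morphology/intensity panel membership reproduces the
  published cardinalities and named features but cannot be guaranteed to
  match the exact membership of closed reference implementations.
* Texture aggregation weights every non-empty matrix equally when
  averaging over slices and directions.
* The convex hull uses a directional-extreme vertex subset (inner
  approximation; negligible for lesion-like shapes, but not exact for
  needle-like geometries).
* The smoothed isosurface slightly shrinks convex bodies (≈ 1.5% volume for
  a 10 mm sphere at 1 mm voxels; the smoothing sigma of 0.7 voxels
  balances staircase suppression against curvature shrinkage so that both
  the sphericity and the scale-invariance contracts hold); voxel-counting volume is reported
  alongside mesh volume.
* Dissemination distances are centroid-based; surface-to-surface
  variants are not implemented.
* The synthetic outcome link is a three-feature logistic model; it cannot
  be used to judge the incremental clinical value of texture features,
  only to verify that the pipeline recovers a known signal without
  leakage.
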