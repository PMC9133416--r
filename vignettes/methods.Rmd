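---
title: "Detecting myocardial scar on delayed-enhancement CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting myocardial scar on delayed-enhancement CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Late gadolinium enhancement MRI (MRI-LGE) is the clinical reference for
imaging myocardial fibrosis, but many patients cannot undergo MRI.
Delayed-enhancement CT (CT-DE), acquired a few minutes after iodinated
contrast injection, retains contrast in fibrotic myocardium and is a
candidate replacement.  The question this package addresses is whether
scar can be detected on CT-DE *quantitatively*: transfer a
reference scar segmentation from the MRI frame onto the CT anatomy,
measure texture (radiomic) features over scarred and remote myocardium,
screen those features for discrimination ability, and classify standard
AHA myocardial segments as scar-bearing or not.

`scarDE` implements that pipeline end to end, together with a synthetic
left-ventricle phantom generator so that every stage is testable without
patient data, which cannot be redistributed for studies of this kind.

# Pipeline stages

## Cross-modality scar transfer (`registerLV`)

The MRI-frame and CT-frame left ventricles are related by an unknown
rigid transform.  Registration proceeds in three steps, each feeding the
next as an initialization:

1. **Major axes** (`alignMajorAxes`): the long axis of each endocardial
   mesh is the dominant eigenvector of its vertex covariance.  The sign
   is fixed anatomically — the axis points from base toward apex, the
   apex being the axial end with the smaller radial spread (the tapered
   end).  The minimal-angle rotation maps one axis onto the other;
   centroids fix the translation.
2. **RV insertion points** (`alignRvInsertions`): rotation about the long
   axis is unresolved by step 1.  The two right-ventricular insertion
   landmarks are projected onto the plane orthogonal to the axis and the
   closed-form 2D Procrustes angle aligns them.
3. **ICP** (`icp`): point-to-point iterative closest point on the whole
   endocardium — nearest-vertex correspondences, closed-form SVD (Kabsch)
   rigid updates.  The objective is the RMS correspondence distance,
   which the update provably never increases for fixed correspondences;
   iteration stops when the improvement drops below `tol` (default
   1e-4 mm) or `maxIter` (default 100).  Point-to-point rather than
   point-to-plane is used because the meshes are clean, complete LV
   shells and the plain variant is the canonical reading of "ICP".

The composed transform carries the MRI-frame scar mesh into the CT frame.
Visual inspection of registrations is replaced by an automatic check
(`registrationQC`) on post-registration apex and base-centroid distances.

## Short-axis masks and the transmural rule (`sliceStack`)

Sixty planes orthogonal to the CT long axis are spaced evenly over the
endocardial extent (end planes inset by half a spacing).  Per plane,
myocardium is rasterized as the region inside the epicardial contour and
outside the endocardial contour, both obtained by exact mesh–plane
intersection and even-odd point-in-contour tests — no 3D watertightness
assumptions.  Scar labeling is deliberately *transmural*: a myocardial
pixel is scar when its angular position about the long axis falls inside
the scar silhouette swept across the wall, so scar at any wall depth
labels the full wall at that location.  This absorbs cardiac-phase
mismatch between modalities.  A slice is valid for analysis when its
non-scar myocardium has at least `min_region_pixels = 16` pixels; scar
regions are analysed under the same minimum.  Texture matrices on
smaller regions are dominated by quantization, which is why a floor is
needed at all.

## The 93 radiomic features

Six families with the canonical counts 18 (first order), 24 (GLCM),
14 (GLDM), 16 (GLSZM), 16 (GLRLM) and 5 (NGTDM), computed in 2D per
slice region.  Definitions follow the widely used open-source reference
implementation of these features (fixed-bin-width discretization, the
default-enabled feature sets).  Conventions that matter for
reproducibility, all fixed here:

* **Discretization**: fixed bin width of 5 HU anchored at the region
  minimum, `level = floor((x - min) / width) + 1`.  Bin width is
  configurable (`radiomicsConfig`).
* **Aggregation**: GLCM and GLRLM matrices are summed over the four
  canonical 2D offsets/directions *before* feature computation, giving a
  single deterministic convention that brute-force oracles can match.
  GLDM, GLSZM and NGTDM use 8-connectivity / 8-neighbourhoods.
* **Degenerate values**: features undefined on a region (GLCM
  correlation with one gray level, skewness of a constant region, and
  similar) are returned as `NA`, then imputed with the cohort median
  before screening or classification.  NGTDM coarseness on a flat region
  takes the conventional 1e6 cap.
* **Per-segment features** are recomputed on the segment's pooled
  myocardial region: intensity samples pooled and texture matrices
  summed across the segment's slices under a shared discretization,
  because the classification ground truth is segment-level.

Every feature is verified against an independently coded brute-force
oracle (explicit loops, BFS flood fill, line walking) to 1e-10 relative
tolerance on 200 random regions in the test suite.

## Combined-energy images (`registerVolumes`, `combineEnergies`)

The two tube-voltage acquisitions are registered rigidly
(mean-squared-error metric, regular-step gradient descent with
central-difference gradients, trilinear resampling; both volumes are
Gaussian-presmoothed for the metric to suppress noise-induced local
minima) and combined voxelwise as `w * high + (1 - w) * low` with
`w` in {0.4, 0.5, 0.6}.  The stated percentage contributions imply
*convex* weights summing to one — a raw sum would double the HU scale.
Because the two noise realisations are independent, the `w = 0.5`
combination has lower noise than the noisier single energy, which is the
mechanism behind combined-energy gains and is asserted on phantoms.
Out-of-field voxels resample to -1024 HU and are excluded from masked
statistics.

## Screening (`screenFeatures`)

Per feature: a two-sided pooled-variance Student's t-test between scar
and non-scar region values (alpha 0.05, raw significance counting; a
Benjamini–Hochberg option exists but is off by default), and a
cross-validated ROC AUC.  "Linear regression" scoring is univariate: the
binary label is regressed on the feature on the training folds, and
since the fitted line is monotone in the feature, the held-out fold is
scored by the feature itself, oriented by the fitted slope's sign and
standardized by the training fold's mean and sd.  Standardizing with
training statistics makes scores commensurable across folds before they
are pooled into one ROC — leaving per-fold intercepts in place would
block-shift each fold's scores by its training prevalence and visibly
inflate the variance of the pooled AUC beyond what the bootstrap
captures.
Folds are *patient-wise* (no patient straddles folds) and stratified on
the patient-level scar prevalence quantile, the natural reading of
"patient-wise stratified" for slice-level rows.  Confidence intervals
are percentile bootstrap over 1,000 resamples of the pooled out-of-fold
(score, label) pairs.  The top 10 features by AUC feed the classifiers;
ties are broken by smaller p (compared on the log scale, since extreme
separations underflow double precision) and then by name, so selection
is deterministic.

## Per-segment classification (`trainEval`)

The LV is partitioned into the AHA 16 segments: basal/mid/apical thirds
by slice index, six 60° sectors in the basal and mid rings, four 90°
sectors apically, angles measured from the anterior RV insertion;
slices beyond the endocardial apex (the 17th, apical-cap segment) are
excluded.  A segment is positive when its scar volume fraction reaches
the threshold (10/20/30% are all computed; 20% is the headline).

Three classifiers are compared — SVM (`e1071`), ridge-penalised logistic
regression (`glmnet`, lambda mapped from the C grid as
`1/(n * C)`), and random forest (`ranger`) — with patient-wise
stratified 5-fold cross-validation, an inner grid search on the training
folds only (small seeded grids: SVM cost {0.1, 1, 10} x kernel
{linear, radial}; trees {100, 300} x depth {unlimited, 8}; C
{0.1, 1, 10}), features scaled to unit column length with training-fold
norms reapplied to test folds, pooled out-of-fold scores for the ROC
AUC with a 1,000-resample bootstrap CI, and sensitivity/specificity at
each classifier's native operating point (zero margin, 0.5 probability,
majority vote), since no operating-point rule is part of the method.
"Scaled to unit length" is read as per-feature (column) unit-norm
scaling; per-row normalisation is available behind a flag of
`scaleUnitLength` users can apply themselves.  Within the grid search,
AUC ties between hyperparameter settings are broken by cross-validated
balanced accuracy, so the chosen model also has a usable operating
point.  The SVM uses a variance-scaled RBF gamma (the "scale" heuristic)
because unit-norm columns otherwise leave the default kernel width
badly mismatched to the data scale.  Permutation importance shuffles
each feature column (10 seeded repeats) and reports the mean drop in
balanced accuracy.

# The phantom: what it emulates and what it does not

`generateCase` builds, per patient:

* **Geometry**: a truncated prolate half-ellipsoid shell (endocardial
  equatorial radius 20 mm, epicardial 28 mm, cavity length 80 mm), which
  has analytic volumes so ground truth is checkable.  RV insertion
  landmarks sit on the epicardial surface at fixed anatomical azimuths.
* **Scar**: one contiguous transmural wedge; the per-patient scar volume
  fraction is drawn from [0.05, 0.20] (a realistic infarct burden range)
  and converted to an angular extent through the analytic shell volume;
  wedge azimuth is random.
* **Misalignment**: a hidden rigid transform (rotation up to 15 degrees,
  translation up to 10 mm) plus 0.5 mm Gaussian vertex noise produces
  the "MRI" meshes; the true transform is stored for evaluation only.
  The noise level makes ICP do real work without breaking convergence.
* **Volumes**: 1 mm isotropic voxels on a grid just enclosing the LV;
  blood pool 250 HU, myocardium 100 HU, scar 100 + 40 HU at unit
  contrast.  Each patient's tissues share a random baseline offset
  (sd 12 HU), emulating patient-specific contrast kinetics; texture
  features are invariant to it, intensity statistics are not — without
  it, intensity features would be implausibly perfect discriminators
  cohort-wide.  Two energy channels differ by a contrast scale (1.0 at
  80 kV vs 0.8 at 100 kV) and noise sd (20 vs 12 HU): the lower voltage
  buys contrast at the price of noise, the usual delayed-enhancement
  trade-off.  The enhancement shift of scar is a free parameter of the
  generator — no published HU statistics exist per energy for this
  protocol — so 40 HU was chosen once as a plausible mid-range value.
* **Scar texture**: inside scar, the noise field is spatially smoothed
  (Gaussian, 2 mm correlation length) and rescaled to 65% of the
  myocardial noise sd.  The correlation length is the homogeneity dial:
  it enlarges the dependence/zone/run structures that the non-uniformity
  texture families measure, so the engineered scar signal is carried by
  spatial structure and not only by a lower noise floor.  Scar texture is therefore more homogeneous than
  remote myocardium — lower discretized gray-level diversity, larger
  dependence/zone structures — which is the dominant signal the
  screening stage is supposed to find, while keeping the scar region
  texturally non-degenerate.

What the phantom does **not** emulate: CT physics (beam hardening,
motion, partial volume), non-transmural or multifocal scar, realistic
anatomy beyond an ellipsoid, inter-energy spatial misalignment beyond
what `registerVolumes` is tested with.  Passing the test suite therefore
demonstrates that the *pipeline machinery* is correct and that it
recovers engineered signals at realistic noise levels — not that the
reported clinical performance would transfer to real patients.

# Numerical choices and edge cases

* Seeds: every stochastic step (cohort generation, fold assignment,
  bootstrap, classifier fitting, permutation importance) is seeded;
  per-case seeds derive deterministically from the master seed.  RNG
  state of the caller is saved and restored around internal seeding.
* Problem sizes: the shipped analyses use the 15-patient cohort scale,
  60 slices per case, ~500-vertex meshes, 1 mm grids — sizes chosen so a
  full end-to-end run completes in minutes on one CPU while texture
  matrices stay well populated.
* Degenerate inputs: spherical meshes raise a principal-axis degeneracy
  error; landmarks on the long axis raise a zero-radius error; planes
  missing the mesh give empty invalid masks rather than errors; segment
  regions below the pixel floor yield flagged-invalid records; folds
  whose training complement lacks a class are merged with a warning.
* The slice stack spans the endocardial axial extent, so the most apical
  myocardium (beyond the endo apex) is not sliced; scar bands sit
  mid-ventricle, so mask-derived scar volumes agree with the voxel
  ground truth to within a few percent.

# Known limitations

Rigid registration only (no deformable refinement); single-plane
nearest-voxel intensity sampling (no slab averaging — the slab thickness
convention is not defined by the method and is left unimplemented); 2D
texture only (no 3D matrices, filtered images or shape features, which
are outside the 93-feature set); the logistic model's regularisation
mapping to the C grid is a convention.  Real-data counts quoted in the
package documentation (significant-feature counts, segment totals,
classifier AUCs) are context from the study this pipeline re-implements,
computed on non-distributable patient images; the package's own tests
assert the structural contracts and phantom-recovery properties instead.
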