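# scarDE — radiomic detection of myocardial scar on delayed-enhancement CT

Delayed-enhancement CT (CT-DE) retains iodinated contrast in fibrotic
myocardium, making it a candidate substitute for late gadolinium
enhancement MRI (MRI-LGE) in patients who cannot undergo MRI.  `scarDE`
implements a quantitative analysis pipeline for that setting:

1. **Scar-label transfer** — three-step rigid registration of the MRI
   left ventricle onto the CT anatomy (major-axis alignment, rotation
   about the long axis from the right-ventricular insertion points,
   whole-endocardium point-to-point ICP), then mapping the MRI scar mesh
   into the CT frame.
2. **Short-axis masking** — 60 planes across the LV; per-plane
   myocardium/scar label masks rasterized from the meshes, with scar
   projected transmurally (scar at any wall depth labels the full wall
   at that angular location).
3. **Radiomics** — 93 features per region in six families: 18 first
   order, 24 GLCM, 14 GLDM, 16 GLSZM, 16 GLRLM, 5 NGTDM, implemented
   from scratch in 2D and verified against brute-force oracles to 1e-10.
4. **Combined-energy imaging** — rigid intensity registration of the
   100 kV volume onto the 80 kV grid and convex voxelwise combination at
   40/50/60% high-energy contribution.
5. **Screening** — per-feature two-sided pooled t-tests (scar vs remote
   myocardium) and ROC AUC from patient-wise stratified 5-fold
   cross-validated linear scores, with 1,000-resample bootstrap CIs;
   top-10 selection by AUC.
6. **Per-segment classification** — AHA 16-segment partition, scar
   ground truth at 10/20/30% segment scar-volume thresholds, and an
   SVM / logistic / random-forest comparison with inner grid search,
   unit-length feature scaling and permutation importance by balanced
   accuracy.

Because patient CT/MRI pairs for this problem are not redistributable,
the package ships a **synthetic LV phantom generator** (`phantomParams`,
`generateCohort`): half-ellipsoid shells with a transmural scar wedge, a
hidden rigid misalignment between "MRI" and "CT" frames, and dual-energy
CT-like volumes in which scar is brighter and texturally more
homogeneous than remote myocardium.  All ground truth (true transform,
true scar label grid, true scar fraction) is retained for evaluation.

## Worked example

```r
library(scarDE)

params <- phantomParams(nPatients = 5, seed = 3)
cohort <- generateCohort(params)

case <- cohort[[1]]
tf <- registerLV(case@mriEndo, case@ctEndo)
tf
#> RigidTransform: rotation 10.408 deg, translation (-6.331, 2.138, 6.752) mm
case@trueMisalignment
#> RigidTransform: rotation 10.355 deg, translation (-6.426, 2.203, 6.766) mm
```

The recovered transform matches the phantom's hidden misalignment to a
fraction of a degree/millimetre.  The full pipeline:

```r
res <- runScarPipeline(cohort, energy = "80kV", seed = 1)
head(res$topFeatures, 3)
#> [1] "gldm.small_dependence_emphasis" "glcm.inverse_variance"
#> [3] "glcm.idm"
res$reports[["svm_20"]]
#> svm @ 20% scar threshold: AUC 0.999 (95% CI 0.996-1.000), sens 1.000, spec 0.983
```

`res$screen` holds the per-feature t/p/AUC/CI table, `res$segments` the
per-segment records (scar volume fraction, labels at each threshold, the
top-10 features), and `res$reports` one entry per classifier/threshold
with AUC, bootstrap CI, sensitivity, specificity and permutation
importance.  On the phantom's engineered signal the screened top 10 is
dominated by homogeneity-sensitive texture features (inverse
difference / inverse variance, dependence and run-length non-uniformity),
and all three classifiers separate scar segments essentially perfectly —
the phantom is a correctness harness, not a difficulty benchmark.

## Layout

- `R/` — S4 classes (`SurfaceMesh`, `RigidTransform`, `ImageVolume`,
  `SliceMask`, `PhantomParams`, `PhantomCase`) and the six pipeline
  stages.
- `tests/testthat/` — unit and property tests per stage plus the
  acceptance suite; brute-force radiomics oracles live in
  `helper-oracles.R`.
- `vignettes/methods.Rmd` — the scientific account: models, parameter
  choices, phantom design, numerical conventions, limitations.
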