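# End-to-end drivers: register -> slice -> features -> screen -> classify,
# for a phantom cohort (or any case-shaped inputs).

#' Register a case and cut its short-axis masks
#'
#' Runs the three-step registration of the MRI endocardium onto the CT
#' endocardium, maps the MRI scar mesh into the CT frame, and rasterizes
#' the short-axis slice stack.
#'
#' @param case a [PhantomCase-class].
#' @param nSlices number of short-axis slices (default 60).
#' @param spacing in-plane pixel spacing (mm).
#' @param minRegionPixels validity threshold per slice.
#' @return List with \code{masks} (the slice stack), \code{transform} (the
#'   recovered MRI-to-CT transform) and \code{scarCt} (scar mesh in the CT
#'   frame).
#' @export
caseSliceMasks <- function(case, nSlices = 60L, spacing = 1,
                           minRegionPixels = 16L) {
  tf <- registerLV(case@mriEndo, case@ctEndo)
  scarCt <- if (case@scarEmpty) case@scarMeshMri else
    applyTransform(case@scarMeshMri, tf)
  masks <- sliceStack(case@ctEndo, case@ctEpi, scarCt, nSlices = nSlices,
                      spacing = spacing, minRegionPixels = minRegionPixels)
  list(masks = masks, transform = tf, scarCt = scarCt)
}

#' Slice-level feature table for one case and energy
#'
#' One row per analysed region: the non-scar myocardium of every valid
#' slice, and the scar region of every slice with enough scar pixels.
#'
#' @param case a [PhantomCase-class].
#' @param masks slice stack from [caseSliceMasks()].
#' @param energy energy label (must exist in \code{case@volumes}).
#' @param config [radiomicsConfig()] list.
#' @return data.frame with provenance columns (patient_id, energy,
#'   slice_index, region, n_pixels) plus the 93 feature columns.
#' @export
caseFeatureTable <- function(case, masks, energy,
                             config = radiomicsConfig()) {
  vol <- case@volumes[[energy]]
  if (is.null(vol)) stop("caseFeatureTable: no volume for energy ", energy)
  rows <- list()
  for (m in masks) {
    if (!length(m@pixels)) next
    for (region in c("nonscar", "scar")) {
      lab <- if (region == "scar") 2L else 1L
      nPix <- sum(m@pixels == lab)
      if (region == "nonscar" && !m@valid) next
      if (nPix < config$minRegionPixels) next
      vals <- extractFeatures(vol, m, lab, config)
      if (is.null(vals)) next
      row <- data.frame(patient_id = case@patientId, energy = energy,
                        slice_index = m@sliceIndex, region = region,
                        n_pixels = nPix, stringsAsFactors = FALSE)
      for (fn in names(vals)) row[[fn]] <- unname(vals[fn])
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Full pipeline over a phantom cohort
#'
#' For every case: three-step registration, scar transfer, 60-slice
#' masking, slice-level 93-feature extraction; then per-feature screening
#' (t-test + cross-validated AUC), top-10 selection, per-segment feature
#' recomputation and the three-classifier comparison at the requested
#' scar-volume thresholds.
#'
#' @param cohort list of [PhantomCase-class] (e.g. [generateCohort()]).
#' @param energy energy label to analyse (default "80kV").
#' @param config [radiomicsConfig()] list.
#' @param nSlices short-axis slice count (default 60).
#' @param topK number of screened features fed to the classifiers.
#' @param thresholds scar-volume thresholds to evaluate.
#' @param kinds classifier kinds to run.
#' @param seed RNG seed for folds/bootstraps/classifiers.
#' @param nBoot bootstrap resamples for CIs.
#' @return List with \code{features} (slice-level table), \code{screen}
#'   (per-feature results), \code{topFeatures}, \code{segments}
#'   (per-segment records), \code{reports} (list of ClassifierReport,
#'   named kind_threshold), and \code{registrations} (per-case transform
#'   diagnostics).
#' @export
runScarPipeline <- function(cohort, energy = "80kV",
                            config = radiomicsConfig(), nSlices = 60L,
                            topK = 10L, thresholds = 0.20,
                            kinds = c("svm", "logistic", "rf"), seed = 0L,
                            nBoot = 1000L) {
  featureRows <- list()
  segmentRows <- list()
  registrations <- list()
  for (case in cohort) {
    sl <- caseSliceMasks(case, nSlices = nSlices,
                         minRegionPixels = config$minRegionPixels)
    registrations[[case@patientId]] <- sl$transform
    ft <- caseFeatureTable(case, sl$masks, energy, config)
    if (!is.null(ft)) featureRows[[case@patientId]] <- ft
    aha <- aha16Assign(sl$masks,
                       case@ctEndo@landmarks[["rv_insertion_anterior"]],
                       case@ctEndo@landmarks[["rv_insertion_inferior"]])
    segmentRows[[case@patientId]] <-
      segmentFeatures(case@volumes[[energy]], sl$masks, aha,
                      topFeatures = NULL, config = config,
                      patientId = case@patientId, energy = energy)
  }
  features <- do.call(rbind, featureRows)
  rownames(features) <- NULL
  screen <- screenFeatures(features, seed = seed, nBoot = nBoot)
  topFeatures <- selectTopK(screen, k = topK)
  segments <- do.call(rbind, segmentRows)
  rownames(segments) <- NULL
  reports <- list()
  for (th in thresholds) {
    for (kind in kinds) {
      reports[[sprintf("%s_%d", kind, round(100 * th))]] <-
        trainEval(segments, kind = kind, threshold = th,
                  featureCols = topFeatures, seed = seed, nBoot = nBoot)
    }
  }
  list(features = features, screen = screen, topFeatures = topFeatures,
       segments = segments, reports = reports,
       registrations = registrations)
}
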