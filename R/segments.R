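# AHA 16-segment partition of the LV, per-segment scar volume fractions
# and labels at the 10/20/30% thresholds, per-segment feature extraction,
# and the three-classifier comparison (SVM / logistic / random forest)
# with patient-wise cross-validation and permutation importance.

#' Assign AHA 16-segment ids to every myocardial pixel
#'
#' The long axis is split into basal/mid/apical thirds by slice index;
#' basal and mid rings are divided into six 60-degree sectors, the apical
#' ring into four 90-degree sectors.  Sector angles are swept about the
#' long axis starting at the anterior RV insertion and running toward the
#' inferior insertion (i.e. through the septum first), numbered in the
#' standard AHA order (1-6 basal, 7-12 mid, 13-16 apical).  Slices beyond
#' the endocardial apex (the apical cap, segment 17 territory) are
#' excluded (id 0).
#'
#' @param masks list of [SliceMask-class] from [sliceStack()].
#' @param rvAnterior anterior RV insertion point (3D), taken from the mask
#'   geometry's generating mesh.
#' @param rvInferior optional inferior RV insertion point; when given, the
#'   angular sweep direction is chosen so the inferior insertion is
#'   reached within the first half turn (the anatomically correct,
#'   septum-first direction); without it the in-plane positive direction
#'   is used.
#' @return List (one per slice) of integer matrices matching the mask
#'   pixel grids: 0 outside myocardium or over the apical cap, else 1-16.
#' @export
aha16Assign <- function(masks, rvAnterior, rvInferior = NULL) {
  if (is.null(rvAnterior)) stop("aha16Assign: missing anterior RV insertion")
  n <- length(masks)
  third <- function(i) {
    if (i < n / 3) 1L else if (i < 2 * n / 3) 2L else 3L
  }
  lapply(masks, function(m) {
    px <- m@pixels
    ids <- matrix(0L, nrow(px), ncol(px))
    if (!length(px) || !m@hasCavity) return(ids)
    d <- rvAnterior - m@planeOrigin
    ang0 <- atan2(sum(d * m@axisV), sum(d * m@axisU))
    flip <- FALSE
    if (!is.null(rvInferior)) {
      di <- rvInferior - m@planeOrigin
      angI <- (atan2(sum(di * m@axisV), sum(di * m@axisU)) - ang0) %%
        (2 * pi)
      flip <- angI > pi
    }
    idx <- which(px > 0L, arr.ind = TRUE)
    if (!nrow(idx)) return(ids)
    uc <- m@gridOffset[1] + (idx[, 1] - 1) * m@pixelSpacing
    vc <- m@gridOffset[2] + (idx[, 2] - 1) * m@pixelSpacing
    phi <- (atan2(vc, uc) - ang0) %% (2 * pi)
    if (flip) phi <- (2 * pi - phi) %% (2 * pi)
    th <- third(m@sliceIndex)
    if (th < 3L) {
      sector <- pmin(floor(phi / (pi / 3)), 5)
      ring <- c(2L, 3L, 4L, 5L, 6L, 1L)  # [0,60) deg after anterior = seg 2
      seg <- ring[sector + 1L] + (th - 1L) * 6L
    } else {
      phi2 <- (phi + pi / 4) %% (2 * pi)
      sector <- pmin(floor(phi2 / (pi / 2)), 3)
      seg <- 13L + sector
    }
    ids[idx] <- as.integer(seg)
    ids
  })
}

#' Per-segment scar volume fraction
#'
#' Scar pixels over total myocardial pixels, per AHA segment, pooled over
#' the slice stack (uniform pixel volume cancels).
#'
#' @param masks list of [SliceMask-class].
#' @param ahaMaps list from [aha16Assign()].
#' @return Named numeric of length 16 (names "1".."16"); NA (with a
#'   warning) for segments containing no myocardium.
#' @export
segmentScarFraction <- function(masks, ahaMaps) {
  scar <- numeric(16); total <- numeric(16)
  for (i in seq_along(masks)) {
    px <- masks[[i]]@pixels
    if (!length(px)) next
    ids <- ahaMaps[[i]]
    for (s in seq_len(16)) {
      inSeg <- ids == s
      total[s] <- total[s] + sum(px > 0L & inSeg)
      scar[s] <- scar[s] + sum(px == 2L & inSeg)
    }
  }
  out <- ifelse(total > 0, scar / total, NA_real_)
  if (any(total == 0))
    warning("segmentScarFraction: empty segment(s) ",
            paste(which(total == 0), collapse = ", "))
  stats::setNames(out, as.character(seq_len(16)))
}

#' Per-segment feature records
#'
#' Recomputes the selected features on each AHA segment's full myocardial
#' region (scar and non-scar pixels pooled across the segment's slices),
#' and attaches the scar volume fraction and the binary labels at the 10,
#' 20 and 30% thresholds.
#'
#' @param volume [ImageVolume-class] the features are measured on.
#' @param masks list of [SliceMask-class].
#' @param ahaMaps list from [aha16Assign()].
#' @param topFeatures character vector of feature names (subset of the 93)
#'   to keep; NULL keeps all 93.
#' @param config [radiomicsConfig()] list.
#' @param patientId,energy identifiers copied into the records.
#' @return data.frame, one row per non-empty segment: \code{patient_id},
#'   \code{energy}, \code{aha_id}, \code{scar_volume_fraction},
#'   \code{label_10}, \code{label_20}, \code{label_30}, \code{valid} and
#'   one column per feature.
#' @export
segmentFeatures <- function(volume, masks, ahaMaps, topFeatures = NULL,
                            config = radiomicsConfig(), patientId = "P?",
                            energy = "?") {
  fractions <- suppressWarnings(segmentScarFraction(masks, ahaMaps))
  if (is.null(topFeatures)) topFeatures <- featureNames93()
  stopifnot(all(topFeatures %in% featureNames93()))
  rows <- list()
  for (s in seq_len(16)) {
    if (is.na(fractions[s])) next
    images <- list()
    for (i in seq_along(masks)) {
      m <- masks[[i]]
      if (!length(m@pixels)) next
      sel <- m@pixels > 0L & ahaMaps[[i]] == s
      if (!any(sel)) next
      images[[length(images) + 1L]] <- regionImageSel(volume, m, sel)
    }
    vals <- extractFeaturesPooled(images, config)
    valid <- !is.null(vals)
    if (!valid)
      vals <- stats::setNames(rep(NA_real_, length(featureNames93())),
                              featureNames93())
    row <- data.frame(patient_id = patientId, energy = energy, aha_id = s,
                      scar_volume_fraction = unname(fractions[s]),
                      label_10 = unname(fractions[s] >= 0.10),
                      label_20 = unname(fractions[s] >= 0.20),
                      label_30 = unname(fractions[s] >= 0.30),
                      valid = valid, stringsAsFactors = FALSE)
    for (fn in topFeatures) row[[fn]] <- unname(vals[fn])
    rows[[length(rows) + 1L]] <- row
  }
  do.call(rbind, rows)
}

#' Scale feature columns to unit Euclidean length
#'
#' Each column is divided by its Euclidean norm computed on the training
#' rows; the returned norms reapply the same scaling to test rows.
#' Zero-norm (constant-zero) columns are flagged and scaled to zeros.
#'
#' @param x numeric matrix (rows = samples).
#' @param norms optional precomputed norms (from a training fit).
#' @return List with \code{scaled} (matrix) and \code{norms} (named
#'   numeric; 0 marks a constant column).
#' @export
scaleUnitLength <- function(x, norms = NULL) {
  x <- as.matrix(x)
  if (is.null(norms)) {
    norms <- sqrt(colSums(x^2))
  }
  sc <- x
  for (j in seq_len(ncol(x)))
    sc[, j] <- if (norms[j] > 0) x[, j] / norms[j] else 0
  list(scaled = sc, norms = norms)
}

# ---- classifier abstraction -------------------------------------------

# default hyperparameter grids (small, seeded, desk-scale)
defaultGrid <- function(kind) {
  switch(kind,
    svm = expand.grid(cost = c(0.1, 1, 10), kernel = c("linear", "radial"),
                      stringsAsFactors = FALSE),
    logistic = expand.grid(C = c(0.1, 1, 10)),
    rf = expand.grid(num.trees = c(100, 300), max.depth = c(0, 8)),
    stop("unknown classifier kind: ", kind))
}

fitClassifier <- function(kind, x, y, params, seed = 0L) {
  y <- as.integer(y)
  fit <- withSeed(seed, switch(kind,
    svm = e1071::svm(x, factor(y, levels = c(0, 1)),
                     kernel = params$kernel, cost = params$cost,
                     # variance-scaled gamma, as in scikit-learn's "scale"
                     gamma = 1 / (ncol(x) * max(stats::var(as.numeric(x)),
                                                1e-12)),
                     scale = FALSE),
    logistic = glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                              lambda = 1 / (nrow(x) * params$C)),
    rf = ranger::ranger(x = x, y = factor(y, levels = c(0, 1)),
                        num.trees = params$num.trees,
                        max.depth = params$max.depth,
                        probability = TRUE, seed = seed,
                        num.threads = 1L)))
  model <- structure(list(kind = kind, fit = fit, params = params,
                          flip = FALSE),
                     class = "scarClassifier")
  if (kind == "svm") {
    # e1071's decision-value sign convention depends on internal label
    # order; orient empirically so higher score = scar on the training set
    tr <- aucFromScores(classifierScore(model, x), y)
    if (!is.na(tr) && tr < 0.5) model$flip <- TRUE
  }
  model
}

# continuous decision score, oriented so higher = scar
classifierScore <- function(model, x) {
  switch(model$kind,
    svm = {
      pr <- stats::predict(model$fit, x, decision.values = TRUE)
      dv <- as.numeric(attr(pr, "decision.values"))
      if (model$flip) -dv else dv
    },
    logistic = as.numeric(stats::predict(model$fit, x, type = "link")),
    rf = {
      p <- stats::predict(model$fit, data = x, num.threads = 1L)$predictions
      p[, "1"]
    })
}

# hard class at the classifier's native operating point
# (zero margin / 0.5 probability / majority vote)
classifierClass <- function(model, x) {
  switch(model$kind,
    svm = as.integer(as.character(stats::predict(model$fit, x))),
    logistic = as.integer(stats::predict(model$fit, x,
                                         type = "response") >= 0.5),
    rf = {
      p <- stats::predict(model$fit, data = x, num.threads = 1L)$predictions
      as.integer(p[, "1"] >= 0.5)
    })
}

balancedAccuracy <- function(truth, pred) {
  sens <- mean(pred[truth == 1L] == 1L)
  spec <- mean(pred[truth == 0L] == 0L)
  (sens + spec) / 2
}

# inner grid search: patient-wise CV AUC per grid row, best row wins
gridSearch <- function(kind, x, y, patients, grid, kInner = 5L, seed = 0L) {
  if (nrow(grid) == 1L) return(grid[1L, , drop = FALSE])
  kUse <- min(kInner, length(unique(patients)))
  folds <- makePatientFolds(patients, strata = tapply(y, patients, mean),
                            k = kUse, seed = seed)
  perf <- vapply(seq_len(nrow(grid)), function(gi) {
    scores <- rep(NA_real_, length(y))
    classes <- rep(NA_integer_, length(y))
    for (f in sort(unique(folds))) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2) next
      m <- fitClassifier(kind, x[tr, , drop = FALSE], y[tr],
                         grid[gi, , drop = FALSE], seed = seed)
      scores[!tr] <- classifierScore(m, x[!tr, , drop = FALSE])
      classes[!tr] <- classifierClass(m, x[!tr, , drop = FALSE])
    }
    ok <- !is.na(scores)
    c(aucFromScores(scores[ok], y[ok]),
      balancedAccuracy(y[ok], classes[ok]))
  }, numeric(2))
  # best cross-validated AUC; balanced accuracy at the native operating
  # point breaks AUC ties
  grid[order(-perf[1, ], -perf[2, ])[1], , drop = FALSE]
}

#' Train and evaluate a per-segment scar classifier
#'
#' Patient-wise stratified 5-fold cross-validation with an inner
#' grid search on the training folds only; features are scaled to unit
#' column length on each training fold and the training norms reapplied to
#' the held-out fold.  Pooled out-of-fold decision scores give the ROC AUC
#' with a 1,000-resample bootstrap 95% CI; sensitivity and specificity are
#' measured at each classifier's native decision threshold.
#'
#' @param records data.frame from [segmentFeatures()] (valid rows are
#'   used).
#' @param kind "svm", "logistic" or "rf".
#' @param threshold scar-volume threshold defining the positive class:
#'   0.10, 0.20 or 0.30.
#' @param featureCols feature column names (default: the 93-feature subset
#'   present in \code{records}).
#' @param grid hyperparameter grid (default [defaultGrid()]).
#' @param k outer folds (default 5).
#' @param seed RNG seed.
#' @param nBoot bootstrap resamples for the AUC CI.
#' @param importance compute permutation feature importance on the pooled
#'   out-of-fold predictions of the last fold's model? (default TRUE).
#' @param nRepeats shuffles per feature for the importance.
#' @return List of class \code{ClassifierReport}: kind, threshold, auc,
#'   ci, sensitivity, specificity, per-feature importance, out-of-fold
#'   scores and labels.
#' @export
trainEval <- function(records, kind = c("svm", "logistic", "rf"),
                      threshold = 0.20, featureCols = NULL, grid = NULL,
                      k = 5L, seed = 0L, nBoot = 1000L, importance = TRUE,
                      nRepeats = 10L) {
  kind <- match.arg(kind)
  records <- records[records$valid, , drop = FALSE]
  if (is.null(featureCols))
    featureCols <- intersect(featureNames93(), names(records))
  if (is.null(grid)) grid <- defaultGrid(kind)
  x <- as.matrix(records[, featureCols, drop = FALSE])
  # cohort-median imputation of undefined features
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- stats::median(x[, j], na.rm = TRUE)
  }
  y <- as.integer(records$scar_volume_fraction >= threshold)
  if (length(unique(y)) < 2)
    stop("trainEval: both classes must be present at threshold ", threshold)
  pats <- as.character(records$patient_id)
  folds <- makePatientFolds(pats, strata = tapply(y, pats, mean), k = k,
                            seed = seed)
  foldIds <- sort(unique(folds))
  for (f in foldIds) {  # merge folds that starve training of a class
    if (length(unique(y[folds != f])) < 2) {
      warning("trainEval: fold ", f, " merged (single-class training set)")
      folds[folds == f] <- foldIds[foldIds != f][1]
    }
  }
  scores <- rep(NA_real_, length(y))
  classes <- rep(NA_integer_, length(y))
  lastModel <- NULL; lastNorms <- NULL; lastTest <- NULL
  for (f in sort(unique(folds))) {
    tr <- folds != f
    sc <- scaleUnitLength(x[tr, , drop = FALSE])
    best <- gridSearch(kind, sc$scaled, y[tr], pats[tr], grid,
                       seed = seed + f)
    model <- fitClassifier(kind, sc$scaled, y[tr], best, seed = seed + f)
    xte <- scaleUnitLength(x[!tr, , drop = FALSE], norms = sc$norms)$scaled
    scores[!tr] <- classifierScore(model, xte)
    classes[!tr] <- classifierClass(model, xte)
    lastModel <- model; lastNorms <- sc$norms; lastTest <- which(!tr)
  }
  auc <- aucFromScores(scores, y)
  ci <- bootstrapAucCI(scores, y, nBoot = nBoot, seed = seed + 101L)
  sens <- mean(classes[y == 1L] == 1L)
  spec <- mean(classes[y == 0L] == 0L)
  imp <- NULL
  if (importance) {
    xte <- scaleUnitLength(x[lastTest, , drop = FALSE],
                           norms = lastNorms)$scaled
    imp <- permutationImportance(lastModel, xte, y[lastTest],
                                 nRepeats = nRepeats, seed = seed + 202L)
  }
  structure(list(kind = kind, threshold = threshold, auc = auc,
                 ciLow = unname(ci[1]), ciHigh = unname(ci[2]),
                 sensitivity = sens, specificity = spec,
                 importance = imp, scores = scores, labels = y,
                 folds = folds),
            class = "ClassifierReport")
}

#' Permutation feature importance by balanced accuracy
#'
#' Shuffles each feature column \code{nRepeats} times (seeded) and reports
#' the mean drop in balanced accuracy relative to the unshuffled baseline.
#'
#' @param model a fitted classifier from inside [trainEval()].
#' @param x test-row feature matrix (already scaled).
#' @param y 0/1 labels for the test rows.
#' @param nRepeats shuffles per feature (default 10).
#' @param seed RNG seed.
#' @return Named numeric: mean balanced-accuracy drop per feature.
#' @export
permutationImportance <- function(model, x, y, nRepeats = 10L, seed = 0L) {
  y <- as.integer(y)
  base <- balancedAccuracy(y, classifierClass(model, x))
  drops <- withSeed(seed, {
    vapply(seq_len(ncol(x)), function(j) {
      mean(vapply(seq_len(nRepeats), function(r) {
        xp <- x
        xp[, j] <- xp[sample.int(nrow(x)), j]
        base - balancedAccuracy(y, classifierClass(model, xp))
      }, numeric(1)))
    }, numeric(1))
  })
  stats::setNames(drops, colnames(x))
}

#' @export
print.ClassifierReport <- function(x, ...) {
  cat(sprintf("%s @ %d%% scar threshold: AUC %.3f (95%% CI %.3f-%.3f), sens %.3f, spec %.3f\n",
              x$kind, round(100 * x$threshold), x$auc, x$ciLow, x$ciHigh,
              x$sensitivity, x$specificity))
  invisible(x)
}
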