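# AHA 16-segment assignment, per-segment scar fractions, unit-length
# scaling, classifier training and permutation importance.

segCase <- function(seed = 42L, ...) {
  p <- smallParams(seed = seed, ...)
  case <- generateCase(p, 0, withVolumes = FALSE)
  sl <- caseSliceMasks(case)
  list(p = p, case = case, masks = sl$masks,
       anterior = meshLandmarks(case@ctEndo)$rv_insertion_anterior)
}

test_that("full-ring phantom populates all 16 segments with balanced
           basal/mid sectors", {
  sc <- segCase()
  aha <- aha16Assign(sc$masks, sc$anterior)
  counts <- integer(16)
  for (i in seq_along(aha)) {
    t <- tabulate(aha[[i]][aha[[i]] > 0], 16)
    counts <- counts + t
  }
  expect_true(all(counts > 0))
  # basal sectors subtend equal angles, so pixel counts are comparable
  basal <- counts[1:6]
  expect_lt(max(basal) / min(basal), 1.35)
  expect_error(aha16Assign(sc$masks, NULL), "insertion")
})

test_that("rotating the anterior insertion by 60 degrees permutes the
           basal/mid segment ids cyclically", {
  sc <- segCase()
  aha1 <- aha16Assign(sc$masks, sc$anterior)
  # rotate the landmark about the long axis (z) by -60 degrees
  R <- rotationAboutAxis(c(0, 0, 1), -pi / 3)
  aha2 <- aha16Assign(sc$masks, as.numeric(R %*% sc$anterior))
  i <- 10  # a basal slice
  a1 <- aha1[[i]]; a2 <- aha2[[i]]
  sel <- a1 > 0 & a2 > 0
  # mapping is one-step cyclic within the basal ring for most pixels
  # (boundary pixels may fall either side of a sector edge)
  shift <- ((a2[sel] - 1L) %% 6L) - ((a1[sel] - 1L) %% 6L)
  agree <- mean(shift %% 6L == (shift[1] %% 6L))
  expect_gt(agree, 0.95)
})

test_that("segment scar fractions: zero-scar case, conservation, range", {
  scz <- segCase(scarFractionRange = c(0, 0))
  ahaZ <- aha16Assign(scz$masks, scz$anterior)
  frZ <- segmentScarFraction(scz$masks, ahaZ)
  expect_true(all(frZ[!is.na(frZ)] == 0))
  sc <- segCase(seed = 43L)
  aha <- aha16Assign(sc$masks, sc$anterior)
  fr <- suppressWarnings(segmentScarFraction(sc$masks, aha))
  expect_true(all(fr[!is.na(fr)] >= 0 & fr[!is.na(fr)] <= 1))
  # conservation: segment scar pixels sum to the stack's scar pixels
  scarTot <- 0
  for (i in seq_along(sc$masks)) {
    px <- sc$masks[[i]]@pixels
    if (length(px)) scarTot <- scarTot + sum(px == 2L & aha[[i]] > 0L)
  }
  segScar <- 0
  for (i in seq_along(sc$masks)) {
    px <- sc$masks[[i]]@pixels
    if (!length(px)) next
    for (s in 1:16) segScar <- segScar + sum(px == 2L & aha[[i]] == s)
  }
  expect_equal(segScar, scarTot)
})

test_that("a wedge confined to one sector loads that segment", {
  p <- smallParams()
  case <- generateCase(p, 0, withVolumes = FALSE)
  anterior <- meshLandmarks(case@ctEndo)$rv_insertion_anterior
  angA <- atan2(anterior[2], anterior[1])
  # 60-degree wedge starting 5 degrees past the anterior insertion, basal
  # z-band only (upper third of an 80 mm LV: z in [-26, 0])
  wedge <- scarDE:::scarWedgeMesh(p, angA + 5 * pi / 180,
                                  angA + 55 * pi / 180, -24, -3)
  masks <- sliceStack(case@ctEndo, case@ctEpi, wedge)
  inferior <- meshLandmarks(case@ctEndo)$rv_insertion_inferior
  aha <- aha16Assign(masks, anterior, inferior)
  fr <- suppressWarnings(segmentScarFraction(masks, aha))
  # wedge sits in basal sector [0,60) after the anterior insertion = seg 2
  expect_gt(fr["2"], 0.5)
  expect_true(all(fr[as.character(7:16)] < 0.05, na.rm = TRUE))
})

test_that("unit-length scaling divides by training-row norms", {
  sc <- scaleUnitLength(matrix(c(3, 4), 2, 1))
  expect_equal(as.numeric(sc$scaled), c(0.6, 0.8))
  X <- matrix(rnorm(20), 5, 4)
  tr <- scaleUnitLength(X)
  expect_equal(unname(sqrt(colSums(tr$scaled^2))), rep(1, 4))
  # test rows reuse the training norms, not their own
  Xtest <- matrix(rnorm(8), 2, 4)
  te <- scaleUnitLength(Xtest, norms = tr$norms)
  expect_equal(te$scaled, sweep(Xtest, 2, tr$norms, "/"))
  # constant-zero column flagged to zeros
  Z <- cbind(rnorm(4), 0)
  expect_true(all(scaleUnitLength(Z)$scaled[, 2] == 0))
})

test_that("classifiers reach perfect metrics on linearly separable
           records and chance on permuted labels", {
  set.seed(12)
  n <- 200
  pats <- rep(sprintf("P%02d", 1:10), each = 20)
  frac <- ifelse(runif(n) < 0.4, runif(n, 0.25, 0.8), runif(n, 0, 0.12))
  rec <- data.frame(patient_id = pats, energy = "80kV",
                    aha_id = rep(1:16, length.out = n),
                    scar_volume_fraction = frac, valid = TRUE,
                    stringsAsFactors = FALSE)
  rec$firstorder.mean <- (frac >= 0.2) * 4 + rnorm(n, sd = 0.3)
  rec$glcm.contrast <- rnorm(n)
  feats <- c("firstorder.mean", "glcm.contrast")
  for (kind in c("svm", "logistic", "rf")) {
    rep_ <- trainEval(rec, kind = kind, threshold = 0.2,
                      featureCols = feats, seed = 5L, nBoot = 100L,
                      importance = FALSE)
    expect_equal(rep_$auc, 1, tolerance = 1e-9)
    expect_equal(rep_$sensitivity, 1)
    expect_equal(rep_$specificity, 1)
    # no patient straddles folds
    perPat <- tapply(rep_$folds, rec$patient_id[rec$valid],
                     function(x) length(unique(x)))
    expect_true(all(perPat == 1))
  }
  # permuted labels: CI covers 0.5
  set.seed(13)
  recP <- rec
  recP$scar_volume_fraction <- sample(frac)
  nullRep <- trainEval(recP, kind = "logistic", threshold = 0.2,
                       featureCols = feats, seed = 6L, nBoot = 200L,
                       importance = FALSE)
  expect_lte(nullRep$ciLow, 0.5)
  expect_gte(nullRep$ciHigh, 0.5)
})

test_that("label monotonicity across scar thresholds", {
  sc <- segCase(seed = 44L)
  aha <- aha16Assign(sc$masks, sc$anterior)
  p <- smallParams(seed = 44L)
  case <- generateCase(p, 0)
  recs <- segmentFeatures(case@volumes[["80kV"]], sc$masks, aha,
                          topFeatures = featureNames93()[1:5],
                          patientId = "P00", energy = "80kV")
  expect_true(all(recs$label_30 <= recs$label_20))
  expect_true(all(recs$label_20 <= recs$label_10))
  expect_true(all(recs$aha_id %in% 1:16))
  expect_lte(nrow(recs), 16)
})

test_that("permutation importance isolates the informative feature", {
  set.seed(14)
  n <- 120
  y <- rep(c(0L, 1L), n / 2)
  x <- cbind(info = y * 2 + rnorm(n, sd = 0.3), noise = rnorm(n))
  model <- scarDE:::fitClassifier("logistic", x, y,
                                  data.frame(C = 1), seed = 1L)
  imp <- permutationImportance(model, x, y, nRepeats = 20L, seed = 2L)
  expect_gt(imp["info"], 0.3)
  expect_lt(abs(imp["noise"]), 0.05)
})
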