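# Radiomic feature engine: hand-computed examples per family, structural
# invariants, and spot checks against the brute-force oracle (the full
# 200-region oracle sweep lives in the acceptance suite).

mkDisc <- function(values, mask = NULL, binWidth = 1) {
  discretize(values, mask, binWidth = binWidth)
}

test_that("fixed-bin-width discretization follows the floor rule", {
  d <- mkDisc(matrix(c(0, 4.9, 5.0, 10), 1), binWidth = 5)
  expect_equal(as.integer(d$gray), c(1L, 1L, 2L, 3L))
  expect_equal(d$nLevels, 3)
  # constant region collapses to one level
  dc <- mkDisc(matrix(7, 3, 3), binWidth = 5)
  expect_equal(unique(as.integer(dc$gray)), 1L)
  # level histogram is invariant to a constant intensity shift
  x <- matrix(runif(36, 0, 30), 6)
  expect_equal(tabulate(mkDisc(x, binWidth = 5)$gray),
               tabulate(mkDisc(x + 123.4, binWidth = 5)$gray))
  expect_error(discretize(matrix(1, 2, 2), matrix(FALSE, 2, 2)), "empty")
})

test_that("first-order features on tiny hand examples", {
  x <- matrix(c(1, 2, 3), 1)
  f <- firstOrderFeatures(c(1, 2, 3), mkDisc(x), pixelVolume = 2)
  expect_equal(unname(f["firstorder.mean"]), 2)
  expect_equal(unname(f["firstorder.energy"]), 14)
  expect_equal(unname(f["firstorder.total_energy"]), 28)
  expect_equal(unname(f["firstorder.range"]), 2)
  # constant region: entropy 0, uniformity 1, variance 0, moments undefined
  fc <- firstOrderFeatures(rep(5, 9), mkDisc(matrix(5, 3, 3)))
  expect_equal(unname(fc["firstorder.entropy"]), 0)
  expect_equal(unname(fc["firstorder.uniformity"]), 1)
  expect_equal(unname(fc["firstorder.variance"]), 0)
  expect_true(is.na(fc["firstorder.skewness"]))
  expect_true(is.na(fc["firstorder.kurtosis"]))
  # histogram entropy equals a direct recomputation on random samples
  set.seed(4)
  xs <- runif(100, 0, 40)
  d <- mkDisc(matrix(xs, 10), binWidth = 5)
  f2 <- firstOrderFeatures(xs, d)
  pr <- as.numeric(table(d$gray)) / 100
  expect_equal(unname(f2["firstorder.entropy"]), -sum(pr * log2(pr)))
})

test_that("GLCM matrix and features match hand enumeration", {
  d <- mkDisc(matrix(c(1, 1, 2, 2), 1))
  P <- glcmMatrix(d, offsets = list(c(0, 1)))
  expect_equal(unclass(P), matrix(c(2, 1, 1, 2) / 6, 2, 2),
               ignore_attr = TRUE)
  f <- glcmFeaturesFromMatrix(P)
  expect_equal(unname(f["glcm.contrast"]), 2 / 6)
  # constant region: single entry 1 at (1,1)
  dc <- mkDisc(matrix(3, 4, 4))
  Pc <- glcmMatrix(dc)
  expect_equal(unclass(Pc), matrix(1, 1, 1), ignore_attr = TRUE)
  fc <- glcmFeaturesFromMatrix(Pc)
  expect_equal(unname(fc["glcm.joint_energy"]), 1)
  expect_equal(unname(fc["glcm.joint_entropy"]), 0)
  expect_equal(unname(fc["glcm.maximum_probability"]), 1)
  expect_equal(unname(fc["glcm.contrast"]), 0)
  expect_true(is.na(fc["glcm.correlation"]))
  expect_true(is.na(fc["glcm.imc1"]))
  # checkerboard with the 4-offset set has no diagonal mass
  chk <- mkDisc(matrix(rep(c(1, 2, 1, 2, 2, 1), 3), 6, 3))
  expect_error(glcmMatrix(chk, offsets = list(c(0, 0))), "zero offset")
  board <- outer(1:6, 1:6, function(i, j) (i + j) %% 2)
  Pb <- glcmMatrix(mkDisc(board), offsets = list(c(0, 1), c(1, 0)))
  expect_equal(sum(diag(Pb)), 0)
  expect_equal(sum(Pb), 1)
})

test_that("GLDM matrix on a constant 3x3 region follows the dependence
           counts 8/5/3 and GLN equals the pixel count", {
  dc <- mkDisc(matrix(1, 3, 3))
  M <- gldmMatrix(dc)
  # dependence sizes d+1: corners 4, edges 6, centre 9
  expect_equal(sum(M), 9)
  expect_equal(M[1, 4], 4)  # 4 corners with 3 dependent neighbours
  expect_equal(M[1, 6], 4)  # 4 edges with 5
  expect_equal(M[1, 9], 1)  # centre with 8
  f <- gldmFeaturesFromMatrix(M)
  expect_equal(unname(f["gldm.gray_level_non_uniformity"]), 9)
  # single pixel: dependence 0
  d1 <- mkDisc(matrix(5, 1, 1))
  M1 <- gldmMatrix(d1)
  expect_equal(unclass(M1), matrix(1, 1, 1), ignore_attr = TRUE)
})

test_that("GLSZM zones on constructed regions", {
  dc <- mkDisc(matrix(2, 4, 4))
  M <- glszmMatrix(dc)
  expect_equal(sum(M), 1)
  expect_equal(M[1, 16], 1)
  expect_equal(unname(glszmFeaturesFromMatrix(M)["glszm.size_zone_non_uniformity"]),
               1)
  # two 2-pixel zones of level 1 and one single pixel of level 2
  img <- matrix(c(1, 1, 2, 9, 9, 9, 1, 1, 9), 3, 3, byrow = TRUE)
  mask <- img != 9
  d <- discretize(img, mask, binWidth = 1)
  Mz <- glszmMatrix(d)
  expect_equal(Mz[1, 2], 2)
  expect_equal(Mz[2, 1], 1)
  ze <- unname(glszmFeaturesFromMatrix(Mz)["glszm.zone_entropy"])
  expect_equal(ze, -(2 / 3 * log2(2 / 3) + 1 / 3 * log2(1 / 3)))
  # zone sizes sum to the masked pixel count
  set.seed(9)
  rr <- randomRegion()
  dr <- discretize(rr$intensities, rr$mask, binWidth = 1)
  Mr <- glszmMatrix(dr)
  sizes <- matrix(rep(seq_len(ncol(Mr)), each = nrow(Mr)), nrow(Mr))
  expect_equal(sum(Mr * sizes), sum(rr$mask))
})

test_that("GLRLM runs on constructed rows", {
  d <- mkDisc(matrix(c(1, 1, 2), 1))
  M <- glrlmMatrix(d, directions = list(c(0, 1)))
  expect_equal(M[1, 2], 1)  # level 1, run length 2
  expect_equal(M[2, 1], 1)  # level 2, run length 1
  # constant N-pixel row: single run, RLN = 1, run percentage = 1/N
  dN <- mkDisc(matrix(4, 1, 7))
  fN <- glrlmFeaturesFromMatrix(glrlmMatrix(dN, directions = list(c(0, 1))))
  expect_equal(unname(fN["glrlm.run_length_non_uniformity"]), 1)
  expect_equal(unname(fN["glrlm.run_percentage"]), 1 / 7)
  # run lengths weighted-sum to pixels per direction
  set.seed(10)
  rr <- randomRegion()
  dr <- discretize(rr$intensities, rr$mask, binWidth = 1)
  Mr <- glrlmMatrix(dr)
  lens <- matrix(rep(seq_len(ncol(Mr)), each = nrow(Mr)), nrow(Mr))
  expect_equal(sum(Mr * lens), 4 * sum(rr$mask))
})

test_that("NGTDM components on hand examples and the coarseness cap", {
  # centre level 2 surrounded by level 1
  img <- matrix(1, 3, 3); img[2, 2] <- 2
  d <- discretize(img, binWidth = 1)
  comp <- ngtdmComponents(d)
  expect_equal(comp$s[2], 1)           # centre deviates by 1 from its mean
  expect_equal(comp$s[1], 32 / 15)     # 4 corners (1/3) + 4 edges (1/5)
  # constant region hits the coarseness cap
  fc <- ngtdmFeatures(mkDisc(matrix(1, 4, 4)))
  expect_equal(unname(fc["ngtdm.coarseness"]), 1e6)
  expect_equal(unname(fc["ngtdm.contrast"]), 0)
})

test_that("feature vector contract: 93 names, family counts, rotation
           consistency, shift behaviour", {
  nm <- featureNames93()
  expect_length(nm, 93)
  fam <- table(sub("\\..*", "", nm))
  expect_equal(as.integer(fam[c("firstorder", "glcm", "gldm", "glszm",
                                "glrlm", "ngtdm")]),
               c(18L, 24L, 14L, 16L, 16L, 5L))
  set.seed(11)
  rr <- randomRegion(maxSide = 10L)
  cfg <- radiomicsConfig(binWidth = 1)
  v <- extractFeaturesPooled(list(rr), cfg)
  expect_equal(names(v), nm)
  # 90-degree rotation leaves all features unchanged (symmetric offsets)
  rot <- list(intensities = t(rr$intensities[nrow(rr$intensities):1, ]),
              mask = t(rr$mask[nrow(rr$mask):1, ]))
  v90 <- extractFeaturesPooled(list(rot), cfg)
  expect_equal(v90, v, tolerance = 1e-12)
  # +50 HU: texture families unchanged, mean shifted by 50
  sh <- list(intensities = rr$intensities + 50, mask = rr$mask)
  vs <- extractFeaturesPooled(list(sh), cfg)
  texture <- nm[!grepl("^firstorder", nm)]
  expect_equal(vs[texture], v[texture], tolerance = 1e-9)
  expect_equal(unname(vs["firstorder.mean"] - v["firstorder.mean"]), 50)
})

test_that("vectorized features match the brute-force oracle on a batch of
           random regions", {
  set.seed(21)
  for (rep in 1:12) {
    rr <- randomRegion(maxSide = 9L, maxLevels = 5L)
    got <- extractFeaturesPooled(list(rr),
                                 radiomicsConfig(binWidth = 1,
                                                 minRegionPixels = 1L))
    want <- oracleAllFeatures(rr$intensities, rr$mask, binWidth = 1)
    for (f in featureNames93()) {
      if (is.na(want[f]) || is.na(got[f])) {
        expect_true(is.na(want[f]) && is.na(got[f]), label = f)
      } else {
        expect_equal(unname(got[f]), unname(want[f]), tolerance = 1e-10,
                     label = f)
      }
    }
  }
})
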