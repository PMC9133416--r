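# The 93 radiomic features: 18 first order, 24 GLCM, 14 GLDM, 16 GLSZM,
# 16 GLRLM, 5 NGTDM.  Definitions follow the widely used open-source
# reference feature set (fixed-bin-width discretization, matrices summed
# over offsets/directions before feature computation).  Degenerate features
# (e.g. GLCM correlation on a single gray level) are returned as NA and
# imputed at cohort level before classification.

log2s <- function(x) ifelse(x > 0, log2(x), 0)  # 0 log 0 := 0

#' The 93 canonical feature names
#'
#' @return Character vector of length 93, namespaced by family
#'   (\code{firstorder.*}, \code{glcm.*}, \code{gldm.*}, \code{glszm.*},
#'   \code{glrlm.*}, \code{ngtdm.*}).
#' @export
featureNames93 <- function() {
  c(paste0("firstorder.",
           c("energy", "total_energy", "entropy", "minimum", "percentile10",
             "percentile90", "maximum", "mean", "median",
             "interquartile_range", "range", "mean_absolute_deviation",
             "robust_mean_absolute_deviation", "root_mean_squared",
             "skewness", "kurtosis", "variance", "uniformity")),
    paste0("glcm.",
           c("autocorrelation", "joint_average", "cluster_prominence",
             "cluster_shade", "cluster_tendency", "contrast", "correlation",
             "difference_average", "difference_entropy",
             "difference_variance", "joint_energy", "joint_entropy", "imc1",
             "imc2", "idm", "idmn", "id", "idn", "inverse_variance",
             "maximum_probability", "sum_entropy", "sum_of_squares", "mcc",
             "sum_average")),
    paste0("gldm.",
           c("small_dependence_emphasis", "large_dependence_emphasis",
             "gray_level_non_uniformity", "dependence_non_uniformity",
             "dependence_non_uniformity_normalized", "gray_level_variance",
             "dependence_variance", "dependence_entropy",
             "low_gray_level_emphasis", "high_gray_level_emphasis",
             "small_dependence_low_gray_level_emphasis",
             "small_dependence_high_gray_level_emphasis",
             "large_dependence_low_gray_level_emphasis",
             "large_dependence_high_gray_level_emphasis")),
    paste0("glszm.",
           c("small_area_emphasis", "large_area_emphasis",
             "gray_level_non_uniformity",
             "gray_level_non_uniformity_normalized",
             "size_zone_non_uniformity",
             "size_zone_non_uniformity_normalized", "zone_percentage",
             "gray_level_variance", "zone_variance", "zone_entropy",
             "low_gray_level_zone_emphasis", "high_gray_level_zone_emphasis",
             "small_area_low_gray_level_emphasis",
             "small_area_high_gray_level_emphasis",
             "large_area_low_gray_level_emphasis",
             "large_area_high_gray_level_emphasis")),
    paste0("glrlm.",
           c("short_run_emphasis", "long_run_emphasis",
             "gray_level_non_uniformity",
             "gray_level_non_uniformity_normalized",
             "run_length_non_uniformity",
             "run_length_non_uniformity_normalized", "run_percentage",
             "gray_level_variance", "run_variance", "run_entropy",
             "low_gray_level_run_emphasis", "high_gray_level_run_emphasis",
             "short_run_low_gray_level_emphasis",
             "short_run_high_gray_level_emphasis",
             "long_run_low_gray_level_emphasis",
             "long_run_high_gray_level_emphasis")),
    paste0("ngtdm.",
           c("coarseness", "contrast", "busyness", "complexity", "strength")))
}

#' First-order intensity statistics (18 features)
#'
#' @param samples numeric vector of region intensities.
#' @param d \code{DiscretizedRegion} of the same region (entropy and
#'   uniformity are computed on discretized levels).
#' @param pixelVolume physical volume per pixel (mm^3) used for total
#'   energy (default 1).
#' @return Named numeric of 18 \code{firstorder.*} values; skewness and
#'   kurtosis are NA on constant regions.
#' @export
firstOrderFeatures <- function(samples, d, pixelVolume = 1) {
  stopifnot(length(samples) >= 1)
  n <- length(samples)
  mu <- mean(samples)
  m2 <- mean((samples - mu)^2)
  q <- stats::quantile(samples, c(0.1, 0.25, 0.75, 0.9), names = FALSE)
  inner <- samples[samples >= q[1] & samples <= q[4]]
  p <- tabulate(d$gray[d$mask], nbins = d$nLevels)
  p <- p / sum(p)
  c(firstorder.energy = sum(samples^2),
    firstorder.total_energy = sum(samples^2) * pixelVolume,
    firstorder.entropy = -sum(p * log2s(p)),
    firstorder.minimum = min(samples),
    firstorder.percentile10 = q[1],
    firstorder.percentile90 = q[4],
    firstorder.maximum = max(samples),
    firstorder.mean = mu,
    firstorder.median = stats::median(samples),
    firstorder.interquartile_range = q[3] - q[2],
    firstorder.range = max(samples) - min(samples),
    firstorder.mean_absolute_deviation = mean(abs(samples - mu)),
    firstorder.robust_mean_absolute_deviation =
      mean(abs(inner - mean(inner))),
    firstorder.root_mean_squared = sqrt(mean(samples^2)),
    firstorder.skewness = if (m2 > 0) mean((samples - mu)^3) / m2^1.5
                          else NA_real_,
    firstorder.kurtosis = if (m2 > 0) mean((samples - mu)^4) / m2^2
                          else NA_real_,
    firstorder.variance = m2,
    firstorder.uniformity = sum(p^2))
}

#' GLCM features (24) from a normalized co-occurrence matrix
#'
#' @param P normalized symmetric co-occurrence matrix from [glcmMatrix()].
#' @return Named numeric of 24 \code{glcm.*} values; correlation, IMC1,
#'   IMC2 and MCC are NA when only one gray level is present.
#' @export
glcmFeaturesFromMatrix <- function(P) {
  ng <- nrow(P)
  i <- matrix(rep(seq_len(ng), ng), ng, ng)
  j <- t(i)
  px <- rowSums(P)
  mux <- sum(seq_len(ng) * px)
  sigx2 <- sum((seq_len(ng) - mux)^2 * px)
  kDiff <- 0:(ng - 1)
  pDiff <- as.numeric(tapply(as.numeric(P), abs(i - j),
                             sum))  # indexed 0..ng-1
  pDiff[is.na(pDiff)] <- 0
  if (length(pDiff) < ng) pDiff <- c(pDiff, rep(0, ng - length(pDiff)))
  kSum <- 2:(2 * ng)
  pSum <- as.numeric(tapply(as.numeric(P), i + j, sum))
  pSum[is.na(pSum)] <- 0
  if (length(pSum) < length(kSum)) pSum <- c(pSum, rep(0, length(kSum) - length(pSum)))
  da <- sum(kDiff * pDiff)
  HX <- -sum(px * log2s(px))
  HXY <- -sum(P * log2s(P))
  pxy <- outer(px, px)
  HXY1 <- -sum(P * log2s(pxy))
  HXY2 <- -sum(pxy * log2s(pxy))
  oneLevel <- sum(px > 0) <= 1
  corr <- if (oneLevel || sigx2 == 0) NA_real_ else
    (sum(i * j * P) - mux^2) / sigx2
  imc1 <- if (oneLevel || HX == 0) NA_real_ else (HXY - HXY1) / HX
  imc2 <- if (oneLevel) NA_real_ else sqrt(max(0, 1 - exp(-2 * (HXY2 - HXY))))
  mcc <- if (oneLevel) NA_real_ else {
    occ <- which(px > 0)
    Q <- matrix(0, length(occ), length(occ))
    for (a in seq_along(occ)) for (b in seq_along(occ)) {
      Q[a, b] <- sum(P[occ[a], occ] * P[occ[b], occ] /
                       (px[occ[a]] * px[occ]))
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    if (length(ev) < 2) NA_real_ else sqrt(max(0, ev[2]))
  }
  c(glcm.autocorrelation = sum(i * j * P),
    glcm.joint_average = mux,
    glcm.cluster_prominence = sum((i + j - 2 * mux)^4 * P),
    glcm.cluster_shade = sum((i + j - 2 * mux)^3 * P),
    glcm.cluster_tendency = sum((i + j - 2 * mux)^2 * P),
    glcm.contrast = sum((i - j)^2 * P),
    glcm.correlation = corr,
    glcm.difference_average = da,
    glcm.difference_entropy = -sum(pDiff * log2s(pDiff)),
    glcm.difference_variance = sum((kDiff - da)^2 * pDiff),
    glcm.joint_energy = sum(P^2),
    glcm.joint_entropy = HXY,
    glcm.imc1 = imc1,
    glcm.imc2 = imc2,
    glcm.idm = sum(P / (1 + (i - j)^2)),
    glcm.idmn = sum(P / (1 + ((i - j) / ng)^2)),
    glcm.id = sum(P / (1 + abs(i - j))),
    glcm.idn = sum(P / (1 + abs(i - j) / ng)),
    glcm.inverse_variance = sum(pDiff[-1] / kDiff[-1]^2),
    glcm.maximum_probability = max(P),
    glcm.sum_entropy = -sum(pSum * log2s(pSum)),
    glcm.sum_of_squares = sigx2,
    glcm.mcc = mcc,
    glcm.sum_average = sum(kSum * pSum))
}

#' GLCM features for a region
#' @param d \code{DiscretizedRegion}.
#' @param offsets passed to [glcmMatrix()].
#' @return Named numeric of 24 values.
#' @export
glcmFeatures <- function(d, offsets = list(c(0, 1), c(1, 1), c(1, 0),
                                           c(1, -1))) {
  glcmFeaturesFromMatrix(glcmMatrix(d, offsets))
}

#' GLDM features (14) from a dependence count matrix
#'
#' @param M count matrix from [gldmMatrix()] (levels x dependence sizes).
#' @return Named numeric of 14 \code{gldm.*} values.
#' @export
gldmFeaturesFromMatrix <- function(M) {
  Nz <- sum(M)
  ng <- nrow(M); nd <- ncol(M)
  i <- matrix(rep(seq_len(ng), nd), ng, nd)
  j <- matrix(rep(seq_len(nd), each = ng), ng, nd)
  p <- M / Nz
  pg <- rowSums(p); pd <- colSums(p)
  mug <- sum(seq_len(ng) * pg)
  mud <- sum(seq_len(nd) * pd)
  c(gldm.small_dependence_emphasis = sum(M / j^2) / Nz,
    gldm.large_dependence_emphasis = sum(M * j^2) / Nz,
    gldm.gray_level_non_uniformity = sum(rowSums(M)^2) / Nz,
    gldm.dependence_non_uniformity = sum(colSums(M)^2) / Nz,
    gldm.dependence_non_uniformity_normalized = sum(colSums(M)^2) / Nz^2,
    gldm.gray_level_variance = sum(p * (i - mug)^2),
    gldm.dependence_variance = sum(p * (j - mud)^2),
    gldm.dependence_entropy = -sum(p * log2s(p)),
    gldm.low_gray_level_emphasis = sum(M / i^2) / Nz,
    gldm.high_gray_level_emphasis = sum(M * i^2) / Nz,
    gldm.small_dependence_low_gray_level_emphasis =
      sum(M / (i^2 * j^2)) / Nz,
    gldm.small_dependence_high_gray_level_emphasis =
      sum(M * i^2 / j^2) / Nz,
    gldm.large_dependence_low_gray_level_emphasis =
      sum(M * j^2 / i^2) / Nz,
    gldm.large_dependence_high_gray_level_emphasis =
      sum(M * i^2 * j^2) / Nz)
}

#' GLDM features for a region
#' @param d \code{DiscretizedRegion}.
#' @param alpha dependence tolerance (default 0).
#' @return Named numeric of 14 values.
#' @export
gldmFeatures <- function(d, alpha = 0L) {
  gldmFeaturesFromMatrix(gldmMatrix(d, alpha))
}

#' GLSZM features (16) from a size-zone count matrix
#'
#' @param M count matrix from [glszmMatrix()] with \code{nPixels}
#'   attribute.
#' @param nPixels masked pixel count (defaults to the attribute).
#' @return Named numeric of 16 \code{glszm.*} values.
#' @export
glszmFeaturesFromMatrix <- function(M, nPixels = attr(M, "nPixels")) {
  Nz <- sum(M)
  ng <- nrow(M); ns <- ncol(M)
  i <- matrix(rep(seq_len(ng), ns), ng, ns)
  s <- matrix(rep(seq_len(ns), each = ng), ng, ns)
  p <- M / Nz
  mug <- sum(i * p); mus <- sum(s * p)
  c(glszm.small_area_emphasis = sum(M / s^2) / Nz,
    glszm.large_area_emphasis = sum(M * s^2) / Nz,
    glszm.gray_level_non_uniformity = sum(rowSums(M)^2) / Nz,
    glszm.gray_level_non_uniformity_normalized = sum(rowSums(M)^2) / Nz^2,
    glszm.size_zone_non_uniformity = sum(colSums(M)^2) / Nz,
    glszm.size_zone_non_uniformity_normalized = sum(colSums(M)^2) / Nz^2,
    glszm.zone_percentage = Nz / nPixels,
    glszm.gray_level_variance = sum(p * (i - mug)^2),
    glszm.zone_variance = sum(p * (s - mus)^2),
    glszm.zone_entropy = -sum(p * log2s(p)),
    glszm.low_gray_level_zone_emphasis = sum(M / i^2) / Nz,
    glszm.high_gray_level_zone_emphasis = sum(M * i^2) / Nz,
    glszm.small_area_low_gray_level_emphasis = sum(M / (i^2 * s^2)) / Nz,
    glszm.small_area_high_gray_level_emphasis = sum(M * i^2 / s^2) / Nz,
    glszm.large_area_low_gray_level_emphasis = sum(M * s^2 / i^2) / Nz,
    glszm.large_area_high_gray_level_emphasis = sum(M * i^2 * s^2) / Nz)
}

#' GLSZM features for a region
#' @param d \code{DiscretizedRegion}.
#' @return Named numeric of 16 values.
#' @export
glszmFeatures <- function(d) {
  glszmFeaturesFromMatrix(glszmMatrix(d))
}

#' GLRLM features (16) from a run-length count matrix
#'
#' @param M count matrix from [glrlmMatrix()] with \code{nPixels} and
#'   \code{nDirections} attributes.
#' @param nPixels,nDirections masked pixel count and number of run
#'   directions (default from attributes).
#' @return Named numeric of 16 \code{glrlm.*} values.
#' @export
glrlmFeaturesFromMatrix <- function(M, nPixels = attr(M, "nPixels"),
                                    nDirections = attr(M, "nDirections")) {
  Nr <- sum(M)
  ng <- nrow(M); nl <- ncol(M)
  i <- matrix(rep(seq_len(ng), nl), ng, nl)
  l <- matrix(rep(seq_len(nl), each = ng), ng, nl)
  p <- M / Nr
  mug <- sum(i * p); mul <- sum(l * p)
  c(glrlm.short_run_emphasis = sum(M / l^2) / Nr,
    glrlm.long_run_emphasis = sum(M * l^2) / Nr,
    glrlm.gray_level_non_uniformity = sum(rowSums(M)^2) / Nr,
    glrlm.gray_level_non_uniformity_normalized = sum(rowSums(M)^2) / Nr^2,
    glrlm.run_length_non_uniformity = sum(colSums(M)^2) / Nr,
    glrlm.run_length_non_uniformity_normalized = sum(colSums(M)^2) / Nr^2,
    glrlm.run_percentage = Nr / (nPixels * nDirections),
    glrlm.gray_level_variance = sum(p * (i - mug)^2),
    glrlm.run_variance = sum(p * (l - mul)^2),
    glrlm.run_entropy = -sum(p * log2s(p)),
    glrlm.low_gray_level_run_emphasis = sum(M / i^2) / Nr,
    glrlm.high_gray_level_run_emphasis = sum(M * i^2) / Nr,
    glrlm.short_run_low_gray_level_emphasis = sum(M / (i^2 * l^2)) / Nr,
    glrlm.short_run_high_gray_level_emphasis = sum(M * i^2 / l^2) / Nr,
    glrlm.long_run_low_gray_level_emphasis = sum(M * l^2 / i^2) / Nr,
    glrlm.long_run_high_gray_level_emphasis = sum(M * i^2 * l^2) / Nr)
}

#' GLRLM features for a region
#' @param d \code{DiscretizedRegion}.
#' @param directions passed to [glrlmMatrix()].
#' @return Named numeric of 16 values.
#' @export
glrlmFeatures <- function(d, directions = list(c(0, 1), c(1, 1), c(1, 0),
                                               c(1, -1))) {
  glrlmFeaturesFromMatrix(glrlmMatrix(d, directions))
}

# conventional cap for coarseness when the NGTDM sum vanishes
NGTDM_COARSENESS_CAP <- 1e6

#' NGTDM features (5) from precomputed components
#'
#' @param comp list from [ngtdmComponents()].
#' @return Named numeric of 5 \code{ngtdm.*} values.
#' @export
ngtdmFeaturesFromComponents <- function(comp) {
  s <- comp$s; n <- comp$n
  Nvp <- comp$nValid
  pi_ <- n / Nvp
  occ <- which(pi_ > 0)
  ngp <- length(occ)
  iv <- seq_along(pi_)
  denomCoarse <- sum(pi_ * s)
  coarseness <- if (denomCoarse > 0) 1 / denomCoarse else NGTDM_COARSENESS_CAP
  contrast <- if (ngp <= 1) 0 else {
    sum(outer(pi_[occ], pi_[occ]) * outer(iv[occ], iv[occ], "-")^2) /
      (ngp * (ngp - 1)) * sum(s) / Nvp
  }
  busyDen <- sum(abs(outer(iv[occ] * pi_[occ], iv[occ] * pi_[occ], "-")))
  busyness <- if (busyDen > 0) sum(pi_ * s) / busyDen else 0
  complexity <- if (ngp == 0) 0 else {
    pij <- outer(pi_[occ], pi_[occ], "+")
    num <- outer(pi_[occ] * s[occ], pi_[occ] * s[occ], "+")
    sum(abs(outer(iv[occ], iv[occ], "-")) * num / pij) / Nvp
  }
  strength <- if (sum(s) > 0)
    sum(outer(pi_[occ], pi_[occ], "+") * outer(iv[occ], iv[occ], "-")^2) /
      sum(s)
  else 0
  c(ngtdm.coarseness = coarseness, ngtdm.contrast = contrast,
    ngtdm.busyness = busyness, ngtdm.complexity = complexity,
    ngtdm.strength = strength)
}

#' NGTDM features for a region
#' @param d \code{DiscretizedRegion}.
#' @return Named numeric of 5 values.
#' @export
ngtdmFeatures <- function(d) {
  ngtdmFeaturesFromComponents(ngtdmComponents(d))
}

#' Radiomics configuration
#'
#' @param binWidth fixed bin width for discretization (HU, default 5).
#' @param alpha GLDM dependence tolerance (default 0).
#' @param minRegionPixels minimum region size for feature extraction.
#' @param pixelVolume physical pixel volume for total energy (mm^3).
#' @return List of settings.
#' @export
radiomicsConfig <- function(binWidth = 5, alpha = 0L, minRegionPixels = 16L,
                            pixelVolume = 1) {
  list(binWidth = binWidth, alpha = alpha,
       minRegionPixels = minRegionPixels, pixelVolume = pixelVolume)
}

# all 93 features from (samples, list of sub-region intensity/mask images)
# sharing one discretization; matrices are summed across sub-regions
computeAllFeatures <- function(images, config) {
  samples <- unlist(lapply(images, function(im) im$intensities[im$mask]))
  lo <- min(samples)
  discs <- lapply(images, function(im) {
    g <- matrix(NA_integer_, nrow(im$intensities), ncol(im$intensities))
    g[im$mask] <- as.integer(floor((im$intensities[im$mask] - lo) /
                                     config$binWidth)) + 1L
    list(gray = g, mask = im$mask)
  })
  ng <- max(unlist(lapply(discs, function(d) max(d$gray, na.rm = TRUE))))
  discs <- lapply(discs, function(d) {
    structure(list(gray = d$gray, mask = d$mask, nLevels = ng),
              class = "DiscretizedRegion")
  })
  padSum <- function(mats) {
    nc <- max(vapply(mats, ncol, 1L))
    out <- matrix(0, ng, nc)
    for (m in mats) out[, seq_len(ncol(m))] <- out[, seq_len(ncol(m))] + m
    out
  }
  # GLCM: sum raw (unnormalized) matrices, then normalize
  glcmRaw <- lapply(discs, glcmMatrix, normalize = FALSE)
  P <- Reduce(`+`, glcmRaw)
  glcmVals <- if (sum(P) == 0) {
    v <- glcmFeaturesFromMatrix(matrix(1, 1, 1))  # single-pixel degenerate
    v[] <- NA_real_
    v
  } else glcmFeaturesFromMatrix(P / sum(P))
  gldmM <- padSum(lapply(discs, gldmMatrix, alpha = config$alpha))
  glszmMats <- lapply(discs, glszmMatrix)
  glszmM <- padSum(glszmMats)
  glrlmMats <- lapply(discs, glrlmMatrix)
  glrlmM <- padSum(glrlmMats)
  nPix <- sum(vapply(discs, function(d) sum(d$mask), 1))
  comps <- lapply(discs, ngtdmComponents)
  comp <- list(s = Reduce(`+`, lapply(comps, `[[`, "s")),
               n = Reduce(`+`, lapply(comps, `[[`, "n")),
               nValid = sum(vapply(comps, `[[`, 1, "nValid")))
  poolDisc <- structure(
    list(gray = matrix(unlist(lapply(discs, function(d) d$gray[d$mask])),
                       ncol = 1),
         mask = matrix(TRUE, nrow = nPix, ncol = 1), nLevels = ng),
    class = "DiscretizedRegion")
  vals <- c(firstOrderFeatures(samples, poolDisc, config$pixelVolume),
            glcmVals,
            gldmFeaturesFromMatrix(gldmM),
            glszmFeaturesFromMatrix(glszmM, nPixels = nPix),
            glrlmFeaturesFromMatrix(glrlmM, nPixels = nPix,
                                    nDirections = 4L),
            ngtdmFeaturesFromComponents(comp))
  names(vals) <- featureNames93()
  attr(vals, "nLevels") <- ng
  attr(vals, "binWidth") <- config$binWidth
  vals
}

# crop the masked region of a slice into a bounding-box intensity image
regionImage <- function(volume, mask, regionLabel) {
  regionImageSel(volume, mask, mask@pixels == as.integer(regionLabel))
}

# same, for an arbitrary pixel selection (e.g. one AHA segment)
regionImageSel <- function(volume, mask, sel) {
  if (!any(sel)) return(NULL)
  idx <- which(sel, arr.ind = TRUE)
  rr <- range(idx[, 1]); cc <- range(idx[, 2])
  sub <- sel[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  rows <- rr[1]:rr[2]; cols <- cc[1]:cc[2]
  uc <- mask@gridOffset[1] + (rows - 1) * mask@pixelSpacing
  vc <- mask@gridOffset[2] + (cols - 1) * mask@pixelSpacing
  pts <- cbind(rep(uc, times = length(vc)), rep(vc, each = length(uc)))
  world <- sweep(outer(pts[, 1], mask@axisU) + outer(pts[, 2], mask@axisV),
                 2, mask@planeOrigin, "+")
  vox <- sweep(world, 2, volume@origin)
  vox <- round(sweep(vox %*% volume@orientation, 2, volume@spacing, "/")) + 1
  d <- dim(volume@voxels)
  ok <- vox[, 1] >= 1 & vox[, 1] <= d[1] & vox[, 2] >= 1 & vox[, 2] <= d[2] &
    vox[, 3] >= 1 & vox[, 3] <= d[3]
  vals <- rep(NA_real_, nrow(vox))
  vals[ok] <- volume@voxels[vox[ok, , drop = FALSE]]
  intens <- matrix(vals, length(rows), length(cols))
  sub[is.na(intens)] <- FALSE
  list(intensities = intens, mask = sub)
}

#' Extract the 93 radiomic features for one slice region
#'
#' Returns NULL (a skip signal, not an error) when the requested region has
#' fewer than \code{minRegionPixels} pixels, so cohort runs continue over
#' invalid slices.
#'
#' @param volume an [ImageVolume-class].
#' @param mask a [SliceMask-class].
#' @param regionLabel 1 = non-scar myocardium, 2 = scar.
#' @param config list from [radiomicsConfig()].
#' @return Named numeric of 93 features (attributes record the bin width
#'   and gray-level count), or NULL for an invalid region.
#' @export
extractFeatures <- function(volume, mask, regionLabel,
                            config = radiomicsConfig()) {
  im <- regionImage(volume, mask, regionLabel)
  if (is.null(im) || sum(im$mask) < config$minRegionPixels) return(NULL)
  computeAllFeatures(list(im), config)
}

#' Extract the 93 features on a pooled multi-slice region
#'
#' Used for per-segment features: intensity samples are pooled and texture
#' matrices summed across the per-slice sub-regions before feature
#' computation, under a shared discretization.
#'
#' @param images list of \code{list(intensities, mask)} sub-region images.
#' @param config list from [radiomicsConfig()].
#' @return Named numeric of 93 features, or NULL when the pooled region is
#'   below \code{minRegionPixels}.
#' @export
extractFeaturesPooled <- function(images, config = radiomicsConfig()) {
  images <- Filter(function(im) !is.null(im) && any(im$mask), images)
  if (!length(images)) return(NULL)
  if (sum(vapply(images, function(im) sum(im$mask), 1)) <
      config$minRegionPixels) return(NULL)
  computeAllFeatures(images, config)
}
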