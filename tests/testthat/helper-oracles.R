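# Brute-force oracle implementations of the 93 radiomic features, coded
# independently of the package internals: explicit per-pixel loops, BFS
# flood fill for zones, naive line walking for runs.  Used to verify the
# vectorized implementations to 1e-10 relative tolerance.

oracleLevels <- function(intens, mask, binWidth) {
  lo <- min(intens[mask])
  g <- matrix(NA_integer_, nrow(intens), ncol(intens))
  for (r in seq_len(nrow(intens))) for (c in seq_len(ncol(intens)))
    if (mask[r, c]) g[r, c] <- floor((intens[r, c] - lo) / binWidth) + 1L
  g
}

oracleQuantile7 <- function(x, p) {
  # linear interpolation between order statistics (type 7)
  x <- sort(x); n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

oracleFirstOrder <- function(samples, g, mask, pixelVolume) {
  n <- length(samples)
  mu <- sum(samples) / n
  m2 <- sum((samples - mu)^2) / n
  m3 <- sum((samples - mu)^3) / n
  m4 <- sum((samples - mu)^4) / n
  p10 <- oracleQuantile7(samples, 0.10); p90 <- oracleQuantile7(samples, 0.90)
  inner <- samples[samples >= p10 & samples <= p90]
  lev <- g[mask]
  counts <- table(lev)
  pr <- as.numeric(counts) / length(lev)
  ent <- 0; for (q in pr) if (q > 0) ent <- ent - q * log2(q)
  c(firstorder.energy = sum(samples^2),
    firstorder.total_energy = sum(samples^2) * pixelVolume,
    firstorder.entropy = ent,
    firstorder.minimum = min(samples),
    firstorder.percentile10 = p10,
    firstorder.percentile90 = p90,
    firstorder.maximum = max(samples),
    firstorder.mean = mu,
    firstorder.median = oracleQuantile7(samples, 0.5),
    firstorder.interquartile_range = oracleQuantile7(samples, 0.75) -
      oracleQuantile7(samples, 0.25),
    firstorder.range = max(samples) - min(samples),
    firstorder.mean_absolute_deviation = sum(abs(samples - mu)) / n,
    firstorder.robust_mean_absolute_deviation =
      sum(abs(inner - mean(inner))) / length(inner),
    firstorder.root_mean_squared = sqrt(sum(samples^2) / n),
    firstorder.skewness = if (m2 > 0) m3 / m2^1.5 else NA_real_,
    firstorder.kurtosis = if (m2 > 0) m4 / m2^2 else NA_real_,
    firstorder.variance = m2,
    firstorder.uniformity = sum(pr^2))
}

oracleGlcmMatrix <- function(g, offsets) {
  ng <- max(g, na.rm = TRUE)
  P <- matrix(0, ng, ng)
  nr <- nrow(g); nc <- ncol(g)
  for (off in offsets) for (r in seq_len(nr)) for (c in seq_len(nc)) {
    r2 <- r + off[1]; c2 <- c + off[2]
    if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
    a <- g[r, c]; b <- g[r2, c2]
    if (is.na(a) || is.na(b)) next
    P[a, b] <- P[a, b] + 1
    P[b, a] <- P[b, a] + 1
  }
  P / sum(P)
}

oracleGlcmFeatures <- function(P) {
  ng <- nrow(P)
  px <- numeric(ng); for (i in 1:ng) px[i] <- sum(P[i, ])
  mux <- 0; for (i in 1:ng) mux <- mux + i * px[i]
  sig2 <- 0; for (i in 1:ng) sig2 <- sig2 + (i - mux)^2 * px[i]
  pd <- numeric(ng)          # |i-j| = 0..ng-1
  ps <- numeric(2 * ng - 1)  # i+j = 2..2ng
  for (i in 1:ng) for (j in 1:ng) {
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + P[i, j]
    ps[i + j - 1] <- ps[i + j - 1] + P[i, j]
  }
  lg <- function(x) if (x > 0) log2(x) else 0
  ac <- 0; cp <- 0; cs <- 0; ct <- 0; con <- 0; je <- 0; jent <- 0
  idm <- 0; idmn <- 0; id <- 0; idn <- 0; ss <- 0; hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    ac <- ac + i * j * P[i, j]
    cp <- cp + (i + j - 2 * mux)^4 * P[i, j]
    cs <- cs + (i + j - 2 * mux)^3 * P[i, j]
    ct <- ct + (i + j - 2 * mux)^2 * P[i, j]
    con <- con + (i - j)^2 * P[i, j]
    je <- je + P[i, j]^2
    jent <- jent - P[i, j] * lg(P[i, j])
    idm <- idm + P[i, j] / (1 + (i - j)^2)
    idmn <- idmn + P[i, j] / (1 + ((i - j) / ng)^2)
    id <- id + P[i, j] / (1 + abs(i - j))
    idn <- idn + P[i, j] / (1 + abs(i - j) / ng)
    ss <- ss + (i - mux)^2 * P[i, j]
    hxy1 <- hxy1 - P[i, j] * lg(px[i] * px[j])
    hxy2 <- hxy2 - px[i] * px[j] * lg(px[i] * px[j])
  }
  da <- 0; for (k in 0:(ng - 1)) da <- da + k * pd[k + 1]
  de <- 0; dv <- 0
  for (k in 0:(ng - 1)) {
    de <- de - pd[k + 1] * lg(pd[k + 1])
    dv <- dv + (k - da)^2 * pd[k + 1]
  }
  iv <- 0; for (k in 1:(ng - 1)) if (ng > 1) iv <- iv + pd[k + 1] / k^2
  se <- 0; sa <- 0
  for (k in 2:(2 * ng)) {
    se <- se - ps[k - 1] * lg(ps[k - 1])
    sa <- sa + k * ps[k - 1]
  }
  hx <- 0; for (i in 1:ng) hx <- hx - px[i] * lg(px[i])
  oneLevel <- sum(px > 0) <= 1
  corr <- if (oneLevel || sig2 == 0) NA_real_ else (ac - mux^2) / sig2
  imc1 <- if (oneLevel || hx == 0) NA_real_ else (jent - hxy1) / hx
  imc2 <- if (oneLevel) NA_real_ else
    sqrt(max(0, 1 - exp(-2 * (hxy2 - jent))))
  mcc <- if (oneLevel) NA_real_ else {
    occ <- which(px > 0)
    Q <- matrix(0, length(occ), length(occ))
    for (a in seq_along(occ)) for (b in seq_along(occ)) {
      acc <- 0
      for (kk in seq_along(occ))
        acc <- acc + P[occ[a], occ[kk]] * P[occ[b], occ[kk]] /
          (px[occ[a]] * px[occ[kk]])
      Q[a, b] <- acc
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    if (length(ev) < 2) NA_real_ else sqrt(max(0, ev[2]))
  }
  c(glcm.autocorrelation = ac, glcm.joint_average = mux,
    glcm.cluster_prominence = cp, glcm.cluster_shade = cs,
    glcm.cluster_tendency = ct, glcm.contrast = con,
    glcm.correlation = corr, glcm.difference_average = da,
    glcm.difference_entropy = de, glcm.difference_variance = dv,
    glcm.joint_energy = je, glcm.joint_entropy = jent, glcm.imc1 = imc1,
    glcm.imc2 = imc2, glcm.idm = idm, glcm.idmn = idmn, glcm.id = id,
    glcm.idn = idn, glcm.inverse_variance = iv,
    glcm.maximum_probability = max(P), glcm.sum_entropy = se,
    glcm.sum_of_squares = ss, glcm.mcc = mcc, glcm.sum_average = sa)
}

oracleNeighbours8 <- function(r, c, nr, nc) {
  out <- NULL
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    r2 <- r + dr; c2 <- c + dc
    if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc)
      out <- rbind(out, c(r2, c2))
  }
  out
}

oracleGldmMatrix <- function(g, alpha) {
  nr <- nrow(g); nc <- ncol(g)
  ng <- max(g, na.rm = TRUE)
  rows <- list()
  maxd <- 1L
  recs <- NULL
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(g[r, c])) next
    dep <- 0L
    nb <- oracleNeighbours8(r, c, nr, nc)
    for (k in seq_len(nrow(nb))) {
      v <- g[nb[k, 1], nb[k, 2]]
      if (!is.na(v) && abs(v - g[r, c]) <= alpha) dep <- dep + 1L
    }
    recs <- rbind(recs, c(g[r, c], dep + 1L))
    maxd <- max(maxd, dep + 1L)
  }
  M <- matrix(0, ng, maxd)
  for (i in seq_len(nrow(recs)))
    M[recs[i, 1], recs[i, 2]] <- M[recs[i, 1], recs[i, 2]] + 1
  M
}

oracleGldmFeatures <- function(M) {
  Nz <- sum(M); ng <- nrow(M); nd <- ncol(M)
  p <- M / Nz
  sde <- 0; lde <- 0; lgl <- 0; hgl <- 0; sdl <- 0; sdh <- 0; ldl <- 0
  ldh <- 0; dent <- 0
  for (i in 1:ng) for (j in 1:nd) {
    sde <- sde + p[i, j] / j^2; lde <- lde + p[i, j] * j^2
    lgl <- lgl + p[i, j] / i^2; hgl <- hgl + p[i, j] * i^2
    sdl <- sdl + p[i, j] / (i^2 * j^2); sdh <- sdh + p[i, j] * i^2 / j^2
    ldl <- ldl + p[i, j] * j^2 / i^2; ldh <- ldh + p[i, j] * i^2 * j^2
    if (p[i, j] > 0) dent <- dent - p[i, j] * log2(p[i, j])
  }
  gln <- 0; for (i in 1:ng) gln <- gln + sum(M[i, ])^2
  dn <- 0; for (j in 1:nd) dn <- dn + sum(M[, j])^2
  mug <- 0; for (i in 1:ng) mug <- mug + i * sum(p[i, ])
  mud <- 0; for (j in 1:nd) mud <- mud + j * sum(p[, j])
  glv <- 0; dv <- 0
  for (i in 1:ng) for (j in 1:nd) {
    glv <- glv + p[i, j] * (i - mug)^2
    dv <- dv + p[i, j] * (j - mud)^2
  }
  c(gldm.small_dependence_emphasis = sde,
    gldm.large_dependence_emphasis = lde,
    gldm.gray_level_non_uniformity = gln / Nz,
    gldm.dependence_non_uniformity = dn / Nz,
    gldm.dependence_non_uniformity_normalized = dn / Nz^2,
    gldm.gray_level_variance = glv, gldm.dependence_variance = dv,
    gldm.dependence_entropy = dent, gldm.low_gray_level_emphasis = lgl,
    gldm.high_gray_level_emphasis = hgl,
    gldm.small_dependence_low_gray_level_emphasis = sdl,
    gldm.small_dependence_high_gray_level_emphasis = sdh,
    gldm.large_dependence_low_gray_level_emphasis = ldl,
    gldm.large_dependence_high_gray_level_emphasis = ldh)
}

# zones by breadth-first flood fill, 8-connected
oracleZones <- function(g) {
  nr <- nrow(g); nc <- ncol(g)
  seen <- matrix(FALSE, nr, nc)
  zones <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(g[r, c]) || seen[r, c]) next
    lev <- g[r, c]
    queue <- list(c(r, c)); seen[r, c] <- TRUE; size <- 0L
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      size <- size + 1L
      nb <- oracleNeighbours8(cur[1], cur[2], nr, nc)
      for (k in seq_len(nrow(nb))) {
        r2 <- nb[k, 1]; c2 <- nb[k, 2]
        if (!seen[r2, c2] && !is.na(g[r2, c2]) && g[r2, c2] == lev) {
          seen[r2, c2] <- TRUE
          queue[[length(queue) + 1L]] <- c(r2, c2)
        }
      }
    }
    zones[[length(zones) + 1L]] <- c(lev, size)
  }
  do.call(rbind, zones)
}

oracleGlszmFeatures <- function(g) {
  zs <- oracleZones(g)
  ng <- max(g, na.rm = TRUE)
  ns <- max(zs[, 2])
  M <- matrix(0, ng, ns)
  for (i in seq_len(nrow(zs))) M[zs[i, 1], zs[i, 2]] <-
      M[zs[i, 1], zs[i, 2]] + 1
  Np <- sum(!is.na(g))
  Nz <- sum(M)
  p <- M / Nz
  sae <- 0; lae <- 0; lgz <- 0; hgz <- 0; sal <- 0; sah <- 0; lal <- 0
  lah <- 0; zent <- 0
  for (i in 1:ng) for (s in 1:ns) {
    sae <- sae + p[i, s] / s^2; lae <- lae + p[i, s] * s^2
    lgz <- lgz + p[i, s] / i^2; hgz <- hgz + p[i, s] * i^2
    sal <- sal + p[i, s] / (i^2 * s^2); sah <- sah + p[i, s] * i^2 / s^2
    lal <- lal + p[i, s] * s^2 / i^2; lah <- lah + p[i, s] * i^2 * s^2
    if (p[i, s] > 0) zent <- zent - p[i, s] * log2(p[i, s])
  }
  gln <- 0; for (i in 1:ng) gln <- gln + sum(M[i, ])^2
  szn <- 0; for (s in 1:ns) szn <- szn + sum(M[, s])^2
  mug <- 0; for (i in 1:ng) mug <- mug + i * sum(p[i, ])
  mus <- 0; for (s in 1:ns) mus <- mus + s * sum(p[, s])
  glv <- 0; zv <- 0
  for (i in 1:ng) for (s in 1:ns) {
    glv <- glv + p[i, s] * (i - mug)^2
    zv <- zv + p[i, s] * (s - mus)^2
  }
  c(glszm.small_area_emphasis = sae, glszm.large_area_emphasis = lae,
    glszm.gray_level_non_uniformity = gln / Nz,
    glszm.gray_level_non_uniformity_normalized = gln / Nz^2,
    glszm.size_zone_non_uniformity = szn / Nz,
    glszm.size_zone_non_uniformity_normalized = szn / Nz^2,
    glszm.zone_percentage = Nz / Np, glszm.gray_level_variance = glv,
    glszm.zone_variance = zv, glszm.zone_entropy = zent,
    glszm.low_gray_level_zone_emphasis = lgz,
    glszm.high_gray_level_zone_emphasis = hgz,
    glszm.small_area_low_gray_level_emphasis = sal,
    glszm.small_area_high_gray_level_emphasis = sah,
    glszm.large_area_low_gray_level_emphasis = lal,
    glszm.large_area_high_gray_level_emphasis = lah)
}

# runs by walking each line in each direction
oracleRuns <- function(g, directions) {
  nr <- nrow(g); nc <- ncol(g)
  runs <- NULL
  starts <- function(dir) {
    s <- NULL
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      rp <- r - dir[1]; cp <- c - dir[2]
      if (rp < 1 || rp > nr || cp < 1 || cp > nc) s <- rbind(s, c(r, c))
    }
    s
  }
  for (dir in directions) {
    st <- starts(dir)
    for (i in seq_len(nrow(st))) {
      r <- st[i, 1]; c <- st[i, 2]
      curLev <- NA_integer_; curLen <- 0L
      while (r >= 1 && r <= nr && c >= 1 && c <= nc) {
        v <- g[r, c]
        if (!is.na(v) && !is.na(curLev) && v == curLev) {
          curLen <- curLen + 1L
        } else {
          if (!is.na(curLev)) runs <- rbind(runs, c(curLev, curLen))
          curLev <- v; curLen <- 1L
        }
        r <- r + dir[1]; c <- c + dir[2]
      }
      if (!is.na(curLev)) runs <- rbind(runs, c(curLev, curLen))
    }
  }
  runs
}

oracleGlrlmFeatures <- function(g, directions) {
  runs <- oracleRuns(g, directions)
  ng <- max(g, na.rm = TRUE)
  nl <- max(runs[, 2])
  M <- matrix(0, ng, nl)
  for (i in seq_len(nrow(runs)))
    M[runs[i, 1], runs[i, 2]] <- M[runs[i, 1], runs[i, 2]] + 1
  Np <- sum(!is.na(g)); D <- length(directions)
  Nr <- sum(M)
  p <- M / Nr
  sre <- 0; lre <- 0; lgr <- 0; hgr <- 0; srl <- 0; srh <- 0; lrl <- 0
  lrh <- 0; rent <- 0
  for (i in 1:ng) for (l in 1:nl) {
    sre <- sre + p[i, l] / l^2; lre <- lre + p[i, l] * l^2
    lgr <- lgr + p[i, l] / i^2; hgr <- hgr + p[i, l] * i^2
    srl <- srl + p[i, l] / (i^2 * l^2); srh <- srh + p[i, l] * i^2 / l^2
    lrl <- lrl + p[i, l] * l^2 / i^2; lrh <- lrh + p[i, l] * i^2 * l^2
    if (p[i, l] > 0) rent <- rent - p[i, l] * log2(p[i, l])
  }
  gln <- 0; for (i in 1:ng) gln <- gln + sum(M[i, ])^2
  rln <- 0; for (l in 1:nl) rln <- rln + sum(M[, l])^2
  mug <- 0; for (i in 1:ng) mug <- mug + i * sum(p[i, ])
  mul <- 0; for (l in 1:nl) mul <- mul + l * sum(p[, l])
  glv <- 0; rv <- 0
  for (i in 1:ng) for (l in 1:nl) {
    glv <- glv + p[i, l] * (i - mug)^2
    rv <- rv + p[i, l] * (l - mul)^2
  }
  c(glrlm.short_run_emphasis = sre, glrlm.long_run_emphasis = lre,
    glrlm.gray_level_non_uniformity = gln / Nr,
    glrlm.gray_level_non_uniformity_normalized = gln / Nr^2,
    glrlm.run_length_non_uniformity = rln / Nr,
    glrlm.run_length_non_uniformity_normalized = rln / Nr^2,
    glrlm.run_percentage = Nr / (Np * D),
    glrlm.gray_level_variance = glv, glrlm.run_variance = rv,
    glrlm.run_entropy = rent, glrlm.low_gray_level_run_emphasis = lgr,
    glrlm.high_gray_level_run_emphasis = hgr,
    glrlm.short_run_low_gray_level_emphasis = srl,
    glrlm.short_run_high_gray_level_emphasis = srh,
    glrlm.long_run_low_gray_level_emphasis = lrl,
    glrlm.long_run_high_gray_level_emphasis = lrh)
}

oracleNgtdmFeatures <- function(g) {
  nr <- nrow(g); nc <- ncol(g)
  ng <- max(g, na.rm = TRUE)
  s <- numeric(ng); n <- numeric(ng); Nvp <- 0
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(g[r, c])) next
    nb <- oracleNeighbours8(r, c, nr, nc)
    vals <- NULL
    for (k in seq_len(nrow(nb))) {
      v <- g[nb[k, 1], nb[k, 2]]
      if (!is.na(v)) vals <- c(vals, v)
    }
    if (is.null(vals)) next
    Nvp <- Nvp + 1
    lev <- g[r, c]
    n[lev] <- n[lev] + 1
    s[lev] <- s[lev] + abs(lev - mean(vals))
  }
  pr <- n / Nvp
  occ <- which(pr > 0); ngp <- length(occ)
  denom <- sum(pr * s)
  coars <- if (denom > 0) 1 / denom else 1e6
  contr <- 0
  if (ngp > 1) {
    acc <- 0
    for (i in occ) for (j in occ) acc <- acc + pr[i] * pr[j] * (i - j)^2
    contr <- acc / (ngp * (ngp - 1)) * sum(s) / Nvp
  }
  bden <- 0
  for (i in occ) for (j in occ) bden <- bden + abs(i * pr[i] - j * pr[j])
  busy <- if (bden > 0) sum(pr * s) / bden else 0
  compl <- 0
  for (i in occ) for (j in occ)
    compl <- compl + abs(i - j) * (pr[i] * s[i] + pr[j] * s[j]) /
      (pr[i] + pr[j])
  compl <- compl / Nvp
  stren <- 0
  if (sum(s) > 0) {
    acc <- 0
    for (i in occ) for (j in occ) acc <- acc + (pr[i] + pr[j]) * (i - j)^2
    stren <- acc / sum(s)
  }
  c(ngtdm.coarseness = coars, ngtdm.contrast = contr,
    ngtdm.busyness = busy, ngtdm.complexity = compl,
    ngtdm.strength = stren)
}

# all 93 oracle features for one masked 2D region
oracleAllFeatures <- function(intens, mask, binWidth = 5, pixelVolume = 1) {
  g <- oracleLevels(intens, mask, binWidth)
  samples <- NULL
  for (r in seq_len(nrow(intens))) for (c in seq_len(ncol(intens)))
    if (mask[r, c]) samples <- c(samples, intens[r, c])
  offs <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  c(oracleFirstOrder(samples, g, mask, pixelVolume),
    oracleGlcmFeatures(oracleGlcmMatrix(g, offs)),
    oracleGldmFeatures(oracleGldmMatrix(g, 0L)),
    oracleGlszmFeatures(g),
    oracleGlrlmFeatures(g, offs),
    oracleNgtdmFeatures(g))
}

# random masked test region with controllable size and gray-level count
randomRegion <- function(maxSide = 12L, maxLevels = 6L, binWidth = 1) {
  nr <- sample(2:maxSide, 1); nc <- sample(2:maxSide, 1)
  intens <- matrix(sample(0:(maxLevels - 1), nr * nc, replace = TRUE) *
                     binWidth + stats::runif(nr * nc, 0, binWidth * 0.49),
                   nr, nc)
  mask <- matrix(stats::runif(nr * nc) < 0.8, nr, nc)
  if (!any(mask)) mask[sample(nr * nc, 2)] <- TRUE
  list(intensities = intens, mask = mask)
}
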