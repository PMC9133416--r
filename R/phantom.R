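# Synthetic left-ventricle phantom cohorts.  The LV is a truncated prolate
# half-ellipsoid shell (analytic volumes make ground truth checkable); scar
# is a contiguous transmural wedge; the "MRI" anatomy is the CT anatomy
# under a hidden rigid misalignment plus vertex noise; per-energy volumes
# differ by a contrast scale and a noise standard deviation, with scar
# noise spatially smoothed so scar texture is more homogeneous than remote
# myocardium.

#' Phantom generator parameters
#'
#' Builds a validated [PhantomParams-class] with defaults sized to the
#' cohort scale of a small single-centre delayed-enhancement CT study
#' (15 patients, two tube voltages, 1 mm voxels).
#'
#' The lower energy ("80kV") gets higher tissue contrast at the price of
#' higher noise, the usual delayed-enhancement trade-off.
#'
#' @param nPatients cohort size.
#' @param endoRadius,epiRadius equatorial endo/epicardial radii (mm).
#' @param lvLength endocardial base-to-apex length (mm).
#' @param scarFractionRange interval in [0, 1] for the per-patient scar
#'   volume fraction.
#' @param scarMeanShift HU added inside scar at unit contrast.
#' @param scarTextureSmoothing correlation length of scar noise (mm).
#' @param scarNoiseScale scar noise sd as a fraction of the myocardial
#'   noise sd of each energy.
#' @param patientBaselineSd between-patient sd of the tissue enhancement
#'   baseline (HU).
#' @param energies energy labels to simulate.
#' @param noiseSdPerEnergy named HU noise sd per energy.
#' @param contrastPerEnergy named contrast scale per energy.
#' @param misalignmentMaxRotation max hidden rotation (degrees).
#' @param misalignmentMaxTranslation max hidden translation (mm).
#' @param vertexNoiseSd Gaussian sd on MRI mesh vertices (mm).
#' @param voxelSpacing isotropic voxel size (mm).
#' @param seed master seed.
#' @return A [PhantomParams-class] object.
#' @export
phantomParams <- function(nPatients = 15L,
                          endoRadius = 20, epiRadius = 28, lvLength = 80,
                          scarFractionRange = c(0.05, 0.20),
                          scarMeanShift = 40,
                          scarTextureSmoothing = 2.0,
                          scarNoiseScale = 0.65,
                          patientBaselineSd = 12,
                          energies = c("80kV", "100kV"),
                          noiseSdPerEnergy = c("80kV" = 20, "100kV" = 12),
                          contrastPerEnergy = c("80kV" = 1.0, "100kV" = 0.8),
                          misalignmentMaxRotation = 15,
                          misalignmentMaxTranslation = 10,
                          vertexNoiseSd = 0.5,
                          voxelSpacing = 1,
                          seed = 1L) {
  p <- new("PhantomParams", nPatients = as.integer(nPatients),
           endoRadius = endoRadius, epiRadius = epiRadius,
           lvLength = lvLength, scarFractionRange = scarFractionRange,
           scarMeanShift = scarMeanShift,
           scarTextureSmoothing = scarTextureSmoothing,
           scarNoiseScale = scarNoiseScale,
           patientBaselineSd = patientBaselineSd,
           energies = energies, noiseSdPerEnergy = noiseSdPerEnergy,
           contrastPerEnergy = contrastPerEnergy,
           misalignmentMaxRotation = misalignmentMaxRotation,
           misalignmentMaxTranslation = misalignmentMaxTranslation,
           vertexNoiseSd = vertexNoiseSd, voxelSpacing = voxelSpacing,
           seed = as.integer(seed))
  p
}

# wall thickness, epicardial half-length
wallThickness <- function(p) p@epiRadius - p@endoRadius
epiLength <- function(p) p@lvLength + wallThickness(p)

# ellipse radius profile r(z) for semi-axes (R radial, L axial), z in [-L, 0]
ellipseRadius <- function(z, R, L) R * sqrt(pmax(0, 1 - (z / L)^2))

# integral of pi * r(z)^2 dz over [z1, z2] for one half-ellipsoid
halfEllipsoidSliceVolume <- function(z1, z2, R, L) {
  z1 <- max(z1, -L); z2 <- min(z2, 0)
  if (z2 <= z1) return(0)
  F <- function(z) z - z^3 / (3 * L^2)
  pi * R^2 * (F(z2) - F(z1))
}

# myocardial shell volume between axial coordinates z1 < z2 (mm^3)
shellVolume <- function(p, z1, z2) {
  halfEllipsoidSliceVolume(z1, z2, p@epiRadius, epiLength(p)) -
    halfEllipsoidSliceVolume(z1, z2, p@endoRadius, p@lvLength)
}

# parametric half-ellipsoid surface mesh, apex at z = -L, open at the base
lvShellMesh <- function(R, L, nTheta = 36L, nPhi = 12L) {
  phi <- seq(0, pi / 2, length.out = nPhi + 1L)[seq_len(nPhi)]
  theta <- seq(0, 2 * pi, length.out = nTheta + 1L)[seq_len(nTheta)]
  g <- expand.grid(theta = theta, phi = phi)   # theta varies fastest
  r <- R * cos(g$phi)
  v <- cbind(r * cos(g$theta), r * sin(g$theta), -L * sin(g$phi))
  apexIdx <- nrow(v) + 1L
  v <- rbind(v, c(0, 0, -L))
  idx <- function(a, p) (p - 1L) * nTheta + ((a - 1L) %% nTheta) + 1L
  faces <- list()
  for (pp in seq_len(nPhi - 1L)) {
    a <- seq_len(nTheta)
    faces[[length(faces) + 1L]] <-
      cbind(idx(a, pp), idx(a + 1L, pp), idx(a, pp + 1L))
    faces[[length(faces) + 1L]] <-
      cbind(idx(a + 1L, pp), idx(a + 1L, pp + 1L), idx(a, pp + 1L))
  }
  a <- seq_len(nTheta)
  faces[[length(faces) + 1L]] <-
    cbind(idx(a, nPhi), idx(a + 1L, nPhi), rep(apexIdx, nTheta))
  SurfaceMesh(v, do.call(rbind, faces))
}

# closed wedge surface bounded by the endo/epi profiles, two azimuthal side
# walls and two axial caps; watertight for ray-casting voxelization
scarWedgeMesh <- function(p, theta0, theta1, z1, z2, nA = 16L, nZ = 10L) {
  th <- seq(theta0, theta1, length.out = nA)
  zs <- seq(z1, z2, length.out = nZ)
  rin <- ellipseRadius(zs, p@endoRadius, p@lvLength)
  rout <- ellipseRadius(zs, p@epiRadius, epiLength(p))
  mk <- function(rr) {
    g <- expand.grid(a = seq_len(nA), z = seq_len(nZ))
    cbind(rr[g$z] * cos(th[g$a]), rr[g$z] * sin(th[g$a]), zs[g$z])
  }
  inner <- mk(rin); outer <- mk(rout)
  v <- rbind(inner, outer)
  iI <- function(a, z) (z - 1L) * nA + a
  iO <- function(a, z) nA * nZ + iI(a, z)
  quads <- list()
  addQuad <- function(p1, p2, p3, p4)
    quads[[length(quads) + 1L]] <<- rbind(cbind(p1, p2, p3), cbind(p1, p3, p4))
  a <- seq_len(nA - 1L); z <- seq_len(nZ - 1L)
  for (zz in z) {
    addQuad(iI(a, zz), iI(a + 1L, zz), iI(a + 1L, zz + 1L), iI(a, zz + 1L))
    addQuad(iO(a, zz), iO(a + 1L, zz), iO(a + 1L, zz + 1L), iO(a, zz + 1L))
  }
  for (zz in z) {  # side walls at theta0 (a = 1) and theta1 (a = nA)
    addQuad(iI(1L, zz), iO(1L, zz), iO(1L, zz + 1L), iI(1L, zz + 1L))
    addQuad(iI(nA, zz), iO(nA, zz), iO(nA, zz + 1L), iI(nA, zz + 1L))
  }
  addQuad(iI(a, 1L), iO(a, 1L), iO(a + 1L, 1L), iI(a + 1L, 1L))    # bottom cap
  addQuad(iI(a, nZ), iO(a, nZ), iO(a + 1L, nZ), iI(a + 1L, nZ))    # top cap
  SurfaceMesh(v, do.call(rbind, quads))
}

# separable Gaussian blur of a 3D array (reflecting edges)
gaussianBlur3d <- function(arr, sigmaVox) {
  if (sigmaVox <= 0) return(arr)
  half <- max(1L, ceiling(3 * sigmaVox))
  k <- stats::dnorm(seq(-half, half), sd = sigmaVox)
  k <- k / sum(k)
  blur1 <- function(a, dim) {
    n <- dim(a)[dim]
    idx <- function(i) pmin(pmax(i, 1L), n)  # clamp at edges
    out <- array(0, dim(a))
    for (j in seq_along(k)) {
      off <- j - half - 1L
      sel <- idx(seq_len(n) + off)
      out <- out + k[j] * switch(dim,
        a[sel, , , drop = FALSE],
        a[, sel, , drop = FALSE],
        a[, , sel, drop = FALSE])
    }
    out
  }
  blur1(blur1(blur1(arr, 1L), 2L), 3L)
}

# deterministic per-case seed below 2^31
caseSeed <- function(seed, patientIndex) {
  as.integer((as.numeric(seed) * 10007 + patientIndex * 7919) %% 2147483647)
}

#' Generate one synthetic patient case
#'
#' Deterministic given \code{(seed, patientIndex)}.  Draws the scar volume
#' fraction and wedge position, builds CT-frame endo/epicardial meshes and
#' the scar wedge, applies a hidden rigid misalignment (plus vertex noise)
#' to produce the MRI-frame meshes, and simulates one CT-like volume per
#' energy in which scar is brighter by \code{scarMeanShift} (scaled by the
#' energy's contrast factor) and has spatially smoothed, lower-variance
#' noise than remote myocardium.
#'
#' @param params a [PhantomParams-class].
#' @param patientIndex 0-based index, < \code{nPatients}.
#' @param withVolumes simulate the voxel volumes (default TRUE); FALSE
#'   returns meshes and ground truth only (volumes empty), useful when
#'   only the registration geometry is needed.  The mesh/misalignment
#'   draws are unaffected.
#' @return A [PhantomCase-class].
#' @export
generateCase <- function(params, patientIndex, withVolumes = TRUE) {
  validObject(params)
  if (patientIndex < 0 || patientIndex >= params@nPatients)
    stop("patientIndex must be in [0, nPatients)")
  set.seed(caseSeed(params@seed, patientIndex))
  p <- params
  L <- p@lvLength; Lepi <- epiLength(p)

  # --- meshes in the CT frame ---
  ctEndo <- lvShellMesh(p@endoRadius, L)
  ctEpi <- lvShellMesh(p@epiRadius, Lepi)
  zIns <- -0.3 * Lepi
  rIns <- ellipseRadius(zIns, p@epiRadius, Lepi)
  thetaAnt <- pi / 3; thetaInf <- pi           # fixed anatomy convention
  lmk <- list(
    rv_insertion_anterior = c(rIns * cos(thetaAnt), rIns * sin(thetaAnt), zIns),
    rv_insertion_inferior = c(rIns * cos(thetaInf), rIns * sin(thetaInf), zIns),
    apex = c(0, 0, -L))
  ctEndo@landmarks <- lmk
  ctEpi@landmarks <- lmk

  # --- scar wedge ---
  fr <- p@scarFractionRange
  f <- stats::runif(1, fr[1], fr[2])
  theta0 <- stats::runif(1, 0, 2 * pi)
  zBand <- c(-0.65, -0.15) * L
  scarEmpty <- f <= 0
  if (!scarEmpty) {
    dTheta <- 2 * pi * f * shellVolume(p, -Lepi, 0) /
      shellVolume(p, zBand[1], zBand[2])
    if (dTheta > 1.95 * pi) {  # widen the band rather than wrap the wedge
      zBand <- c(-0.8, -0.05) * L
      dTheta <- 2 * pi * f * shellVolume(p, -Lepi, 0) /
        shellVolume(p, zBand[1], zBand[2])
    }
    scarMeshCt <- scarWedgeMesh(p, theta0, theta0 + dTheta, zBand[1], zBand[2])
  } else {
    dTheta <- 0
    scarMeshCt <- SurfaceMesh(matrix(numeric(0), 0, 3))
  }

  # --- hidden misalignment: trueMisalignment maps MRI frame -> CT frame ---
  maxRot <- p@misalignmentMaxRotation * pi / 180
  axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
  ang <- stats::runif(1, 0, maxRot)
  tr <- stats::rnorm(3); tr <- tr / sqrt(sum(tr^2))
  tr <- tr * stats::runif(1, 0, p@misalignmentMaxTranslation)
  trueMis <- RigidTransform(rotationAboutAxis(axis, ang), tr)
  toMri <- invertTransform(trueMis)
  jitter <- function(mesh) {
    if (!nrow(mesh@vertices)) return(mesh)
    m <- applyTransform(mesh, toMri)
    m@vertices <- m@vertices +
      matrix(stats::rnorm(length(m@vertices), sd = p@vertexNoiseSd),
             ncol = 3)
    m
  }
  mriEndo <- jitter(ctEndo)
  mriEpi <- jitter(ctEpi)
  scarMeshMri <- if (scarEmpty) scarMeshCt else applyTransform(scarMeshCt, toMri)

  # --- voxel grid enclosing the LV ---
  s <- p@voxelSpacing
  margin <- 4
  xr <- c(-(p@epiRadius + margin), p@epiRadius + margin)
  zr <- c(-(Lepi + margin), margin)
  xs <- seq(xr[1], xr[2], by = s)
  zs <- seq(zr[1], zr[2], by = s)
  nx <- length(xs); nz <- length(zs)
  origin <- c(xr[1], xr[1], zr[1])

  X <- array(rep(xs, times = nx * nz), c(nx, nx, nz))
  Y <- array(rep(rep(xs, each = nx), times = nz), c(nx, nx, nz))
  Z <- array(rep(zs, each = nx * nx), c(nx, nx, nz))
  r2 <- X^2 + Y^2
  insideEndo <- Z <= 0 & Z >= -L & r2 <= ellipseRadius(Z, p@endoRadius, L)^2
  insideEpi <- Z <= 0 & Z >= -Lepi & r2 <= ellipseRadius(Z, p@epiRadius, Lepi)^2
  shell <- insideEpi & !insideEndo
  theta <- (atan2(Y, X) - theta0) %% (2 * pi)
  scarVox <- if (scarEmpty) array(FALSE, dim(shell)) else
    shell & theta <= dTheta & Z >= zBand[1] & Z <= zBand[2]

  # tissue map at unit contrast; all tissues share a per-patient baseline
  # offset (patient-specific contrast kinetics), which texture features are
  # invariant to but intensity statistics feel
  baseShift <- stats::rnorm(1, sd = p@patientBaselineSd)
  base <- array(0, dim(shell))
  base[insideEndo] <- 250 + baseShift   # contrast-filled blood pool
  base[shell] <- 100 + baseShift        # remote myocardium
  base[scarVox] <- 100 + baseShift + p@scarMeanShift

  volumes <- list()
  sigmaVox <- p@scarTextureSmoothing / s
  for (en in if (withVolumes) p@energies else character(0)) {
    sd_e <- p@noiseSdPerEnergy[[en]]
    con_e <- p@contrastPerEnergy[[en]]
    noise <- array(stats::rnorm(length(base), sd = sd_e), dim(base))
    if (any(scarVox) && sigmaVox > 0) {
      smooth <- gaussianBlur3d(
        array(stats::rnorm(length(base), sd = 1), dim(base)), sigmaVox)
      target <- p@scarNoiseScale * sd_e
      smooth <- smooth * (target / stats::sd(as.numeric(smooth)))
      noise[scarVox] <- smooth[scarVox]
    }
    volumes[[en]] <- ImageVolume(con_e * base + noise, spacing = rep(s, 3),
                                 origin = origin)
  }

  label <- ImageVolume(array(as.numeric(scarVox), dim(scarVox)),
                       spacing = rep(s, 3), origin = origin)
  new("PhantomCase", patientId = sprintf("P%02d", patientIndex),
      ctEndo = ctEndo, ctEpi = ctEpi, mriEndo = mriEndo, mriEpi = mriEpi,
      scarMeshMri = scarMeshMri, trueMisalignment = trueMis,
      volumes = volumes, trueScarLabel = label, trueScarFraction = f,
      scarEmpty = scarEmpty)
}

#' Generate a synthetic cohort
#'
#' One [PhantomCase-class] per patient, with per-case seeds derived
#' deterministically from the master seed; identical parameters give
#' identical cohorts.
#'
#' @param params a [PhantomParams-class].
#' @param withVolumes passed to [generateCase()].
#' @return List of [PhantomCase-class] objects with unique patient ids.
#' @export
generateCohort <- function(params, withVolumes = TRUE) {
  validObject(params)
  lapply(seq_len(params@nPatients) - 1L,
         function(i) generateCase(params, i, withVolumes = withVolumes))
}

#' Voxelize a closed surface mesh onto a volume grid
#'
#' Marks every voxel whose centre lies inside the mesh, by counting
#' ray-triangle crossings along +x (even-odd rule).  Intended for
#' watertight meshes such as the phantom scar wedge.
#'
#' @param volume an [ImageVolume-class] supplying the grid.
#' @param mesh a closed [SurfaceMesh-class].
#' @return 3D logical array matching \code{volume}'s voxel grid.
#' @export
voxelizeMesh <- function(volume, mesh) {
  d <- dim(volume@voxels)
  out <- array(FALSE, d)
  if (!nrow(mesh@faces)) return(out)
  sp <- volume@spacing; o <- volume@origin
  ys <- o[2] + (seq_len(d[2]) - 1) * sp[2]
  zs <- o[3] + (seq_len(d[3]) - 1) * sp[3]
  v <- mesh@vertices; f <- mesh@faces
  # tiny deterministic offset avoids rays hitting edges/vertices exactly
  eps <- c(sp[2], sp[3]) * 1e-4
  g <- expand.grid(y = ys + eps[1], z = zs + eps[2])
  ny <- length(ys)
  xsHit <- vector("list", nrow(g))
  for (i in seq_len(nrow(g))) xsHit[[i]] <- numeric(0)
  for (t in seq_len(nrow(f))) {
    p1 <- v[f[t, 1], ]; p2 <- v[f[t, 2], ]; p3 <- v[f[t, 3], ]
    ymin <- min(p1[2], p2[2], p3[2]); ymax <- max(p1[2], p2[2], p3[2])
    zmin <- min(p1[3], p2[3], p3[3]); zmax <- max(p1[3], p2[3], p3[3])
    sel <- which(g$y >= ymin & g$y <= ymax & g$z >= zmin & g$z <= zmax)
    if (!length(sel)) next
    # 2D barycentric test in the (y, z) plane
    d1 <- c(p2[2] - p1[2], p2[3] - p1[3])
    d2 <- c(p3[2] - p1[2], p3[3] - p1[3])
    det <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(det) < 1e-12) next
    wy <- g$y[sel] - p1[2]; wz <- g$z[sel] - p1[3]
    b1 <- (wy * d2[2] - wz * d2[1]) / det
    b2 <- (wz * d1[1] - wy * d1[2]) / det
    inside <- b1 >= 0 & b2 >= 0 & (b1 + b2) <= 1
    if (!any(inside)) next
    hit <- sel[inside]
    xhit <- p1[1] + b1[inside] * (p2[1] - p1[1]) + b2[inside] * (p3[1] - p1[1])
    for (k in seq_along(hit))
      xsHit[[hit[k]]] <- c(xsHit[[hit[k]]], xhit[k])
  }
  xsGrid <- o[1] + (seq_len(d[1]) - 1) * sp[1]
  for (i in seq_len(nrow(g))) {
    hx <- xsHit[[i]]
    if (length(hx) < 2) next
    hx <- sort(hx)
    iy <- ((i - 1) %% ny) + 1
    iz <- ((i - 1) %/% ny) + 1
    # voxels whose x lies inside an odd interval are interior
    inside <- findInterval(xsGrid, hx) %% 2 == 1
    out[inside, iy, iz] <- TRUE
  }
  out
}

#' Write a phantom case to disk
#'
#' Meshes as ASCII PLY, volumes and the ground-truth label as NIfTI
#' (.nii.gz), landmarks and the true transform as a JSON sidecar.
#'
#' @param case a [PhantomCase-class].
#' @param dir output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
writePhantomCase <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  put <- function(name, path) paths[[name]] <<- path
  for (nm in c("ctEndo", "ctEpi", "mriEndo", "mriEpi", "scarMeshMri")) {
    f <- file.path(dir, paste0(nm, ".ply"))
    writePLY(slot(case, nm), f); put(nm, f)
  }
  for (en in names(case@volumes)) {
    f <- file.path(dir, paste0("volume_", gsub("\\W", "", en), ".nii.gz"))
    writeVolumeNIfTI(case@volumes[[en]], f); put(paste0("volume_", en), f)
  }
  f <- file.path(dir, "true_scar_label.nii.gz")
  writeVolumeNIfTI(case@trueScarLabel, f); put("trueScarLabel", f)
  f <- file.path(dir, "sidecar.json")
  jsonlite::write_json(list(
    patient_id = case@patientId,
    true_scar_fraction = case@trueScarFraction,
    scar_empty = case@scarEmpty,
    landmarks_ct = case@ctEndo@landmarks,
    landmarks_mri = case@mriEndo@landmarks,
    true_misalignment = list(
      rotation = as.numeric(t(case@trueMisalignment@rotation)),
      translation = case@trueMisalignment@translation)),
    f, auto_unbox = TRUE, digits = NA)
  put("sidecar", f)
  invisible(unlist(paths))
}

#' Write a phantom cohort with a CSV manifest
#'
#' @param cohort list of [PhantomCase-class] objects.
#' @param dir output directory.
#' @return Path of the manifest CSV, invisibly.
#' @export
writePhantomCohort <- function(cohort, dir) {
  rows <- lapply(cohort, function(case) {
    sub <- file.path(dir, case@patientId)
    writePhantomCase(case, sub)
    data.frame(patient_id = case@patientId, path = sub,
               true_scar_fraction = case@trueScarFraction,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  f <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, f, row.names = FALSE)
  invisible(f)
}
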