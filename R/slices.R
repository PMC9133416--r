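# Short-axis reslicing: 60 planes orthogonal to the LV long axis, per-plane
# myocardium/scar label masks rasterized from the meshes.  Scar membership
# is decided by the in-plane angular footprint of the scar silhouette, so
# any scar at a wall location labels the full wall there (transmural rule).

#' Short-axis cutting planes
#'
#' Planes orthogonal to the endocardial principal axis, origins evenly
#' spaced along the mesh's axial extent with the end planes inset by half a
#' spacing.  Slice 0 is basal, the last slice apical.
#'
#' @param endo endocardial [SurfaceMesh-class].
#' @param nSlices number of planes (default 60).
#' @return List with \code{origins} (nSlices x 3), \code{normal} (unit long
#'   axis, base-to-apex), and \code{spacing} (axial distance between
#'   consecutive planes, mm).
#' @export
shortAxisPlanes <- function(endo, nSlices = 60L) {
  stopifnot(nSlices >= 1L)
  axis <- principalAxis(endo)
  v <- endo@vertices
  s <- as.numeric(v %*% axis)
  smin <- min(s); smax <- max(s)
  spacing <- (smax - smin) / nSlices
  ctr <- colMeans(v)
  sc <- sum(ctr * axis)
  # axis points base -> apex, i.e. s increases toward the apex
  si <- smin + (seq_len(nSlices) - 0.5) * spacing
  origins <- t(vapply(si, function(x) ctr + (x - sc) * axis, numeric(3)))
  list(origins = origins, normal = axis, spacing = spacing)
}

# in-plane orthonormal basis; u aligned with the anterior RV insertion
# direction when the mesh carries that landmark, else a deterministic
# fallback derived from the normal
planeBasis <- function(normal, origin, anterior = NULL) {
  n <- normal / sqrt(sum(normal^2))
  if (!is.null(anterior)) {
    d <- anterior - origin
    u <- d - sum(d * n) * n
    if (sqrt(sum(u^2)) > 1e-9) {
      u <- u / sqrt(sum(u^2))
      v <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3],
             n[1] * u[2] - n[2] * u[1])
      return(list(u = u, v = v))
    }
  }
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * n) * n; u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  list(u = u, v = v)
}

# intersect mesh triangles with the plane; returns 2D segments (u,v coords)
# as a matrix with columns x1, y1, x2, y2
meshPlaneSegments <- function(mesh, origin, normal, u, v) {
  verts <- mesh@vertices; faces <- mesh@faces
  if (!nrow(faces)) return(matrix(numeric(0), 0, 4))
  d <- as.numeric(sweep(verts, 2, origin) %*% normal)
  dv <- matrix(d[faces], ncol = 3)
  crosses <- (apply(dv, 1, min) < 0) & (apply(dv, 1, max) > 0)
  if (!any(crosses)) return(matrix(numeric(0), 0, 4))
  proj <- cbind(as.numeric(sweep(verts, 2, origin) %*% u),
                as.numeric(sweep(verts, 2, origin) %*% v))
  segs <- matrix(numeric(0), 0, 4)
  for (fi in which(crosses)) {
    ids <- faces[fi, ]; dd <- d[ids]
    pts <- matrix(numeric(0), 0, 2)
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      d1 <- dd[e[1]]; d2 <- dd[e[2]]
      if ((d1 < 0) != (d2 < 0)) {
        t <- d1 / (d1 - d2)
        pts <- rbind(pts, proj[ids[e[1]], ] +
                       t * (proj[ids[e[2]], ] - proj[ids[e[1]], ]))
      }
    }
    if (nrow(pts) == 2) segs <- rbind(segs, c(pts[1, ], pts[2, ]))
  }
  segs
}

# even-odd point-in-contour test against an (unordered) 2D segment soup
pointsInContour <- function(px, py, segs) {
  inside <- rep(FALSE, length(px))
  if (!nrow(segs)) return(inside)
  for (i in seq_len(nrow(segs))) {
    ax <- segs[i, 1]; ay <- segs[i, 2]; bx <- segs[i, 3]; by <- segs[i, 4]
    if (ay == by) next
    straddles <- (ay > py) != (by > py)
    if (!any(straddles)) next
    xcross <- ax + (py - ay) / (by - ay) * (bx - ax)
    inside <- xor(inside, straddles & px < xcross)
  }
  inside
}

# angular bins (about the in-plane origin) covered by a segment soup; each
# segment marks the full shorter arc between its endpoint angles, which is
# exact for chords not subtending the origin
coveredAngleBins <- function(segs, nBins) {
  covered <- rep(FALSE, nBins)
  if (!nrow(segs)) return(covered)
  binOf <- function(a) floor((a %% (2 * pi)) / (2 * pi) * nBins) + 1L
  for (i in seq_len(nrow(segs))) {
    a1 <- atan2(segs[i, 2], segs[i, 1]) %% (2 * pi)
    a2 <- atan2(segs[i, 4], segs[i, 3]) %% (2 * pi)
    d <- (a2 - a1) %% (2 * pi)
    if (d > pi) { tmp <- a1; a1 <- a2; a2 <- tmp; d <- 2 * pi - d }
    b1 <- binOf(a1)
    nSpan <- ceiling(d / (2 * pi) * nBins) + 1L
    covered[((b1 - 1L + seq_len(nSpan) - 1L) %% nBins) + 1L] <- TRUE
  }
  covered
}

#' Rasterize one short-axis slice
#'
#' Myocardium = pixels inside the epicardial contour and outside the
#' endocardial contour.  Scar = myocardial pixels whose angular position
#' (about the long axis) falls inside the scar mesh's in-plane silhouette,
#' swept across the full wall thickness: any scar at a wall location labels
#' the whole wall there, regardless of its transmural depth.
#'
#' @param endo,epi,scar [SurfaceMesh-class] objects in the same (CT) frame;
#'   \code{scar} may be empty.
#' @param origin,normal plane origin (on the long axis) and unit normal.
#' @param spacing in-plane pixel spacing (mm, default 1).
#' @param sliceIndex 0-based index stored in the mask.
#' @param minRegionPixels a slice is \code{valid} when its non-scar
#'   myocardium has at least this many pixels (default 16).
#' @param anterior optional anterior RV insertion point fixing the in-plane
#'   u axis.
#' @return A [SliceMask-class]; a plane missing the mesh gives an empty,
#'   invalid mask.
#' @export
rasterizeSlice <- function(endo, epi, scar, origin, normal, spacing = 1,
                           sliceIndex = 0L, minRegionPixels = 16L,
                           anterior = NULL) {
  if (is.null(anterior)) anterior <- endo@landmarks[["rv_insertion_anterior"]]
  basis <- planeBasis(normal, origin, anterior)
  u <- basis$u; v <- basis$v
  segsEpi <- meshPlaneSegments(epi, origin, normal, u, v)
  emptyMask <- function() {
    new("SliceMask", sliceIndex = as.integer(sliceIndex),
        planeOrigin = as.numeric(origin), planeNormal = as.numeric(normal),
        axisU = u, axisV = v, gridOffset = c(0, 0),
        pixels = matrix(integer(0), 0, 0), pixelSpacing = spacing,
        valid = FALSE, hasCavity = FALSE)
  }
  if (!nrow(segsEpi)) return(emptyMask())
  segsEndo <- meshPlaneSegments(endo, origin, normal, u, v)
  xr <- range(segsEpi[, c(1, 3)]); yr <- range(segsEpi[, c(2, 4)])
  x0 <- floor((xr[1] - spacing) / spacing) * spacing
  y0 <- floor((yr[1] - spacing) / spacing) * spacing
  nxp <- ceiling((xr[2] + spacing - x0) / spacing) + 1L
  nyp <- ceiling((yr[2] + spacing - y0) / spacing) + 1L
  pxu <- x0 + (seq_len(nxp) - 1L) * spacing
  pxv <- y0 + (seq_len(nyp) - 1L) * spacing
  gx <- rep(pxu, times = nyp)
  gy <- rep(pxv, each = nxp)
  insideEpi <- pointsInContour(gx, gy, segsEpi)
  insideEndo <- pointsInContour(gx, gy, segsEndo)
  myo <- insideEpi & !insideEndo
  labels <- matrix(0L, nxp, nyp)
  labels[myo] <- 1L
  if (!is.null(scar) && nrow(scar@faces)) {
    segsScar <- meshPlaneSegments(scar, origin, normal, u, v)
    if (nrow(segsScar)) {
      nBins <- 720L
      covered <- coveredAngleBins(segsScar, nBins)
      ang <- atan2(gy, gx) %% (2 * pi)
      bins <- floor(ang / (2 * pi) * nBins) + 1L
      labels[myo & covered[bins]] <- 2L
    }
  }
  valid <- sum(labels == 1L) >= minRegionPixels
  new("SliceMask", sliceIndex = as.integer(sliceIndex),
      planeOrigin = as.numeric(origin), planeNormal = as.numeric(normal),
      axisU = u, axisV = v, gridOffset = c(x0, y0), pixels = labels,
      pixelSpacing = spacing, valid = valid, hasCavity = any(insideEndo))
}

#' Cut a full stack of short-axis slice masks
#'
#' @param endo,epi,scar meshes in the CT frame (\code{scar} may be NULL or
#'   empty).
#' @param nSlices number of slices (default 60).
#' @param spacing in-plane pixel spacing (mm).
#' @param minRegionPixels validity threshold per slice.
#' @return List of [SliceMask-class] with attributes \code{sliceSpacing}
#'   (axial inter-plane distance, mm) and \code{normal}.
#' @export
sliceStack <- function(endo, epi, scar = NULL, nSlices = 60L, spacing = 1,
                       minRegionPixels = 16L) {
  planes <- shortAxisPlanes(endo, nSlices)
  masks <- lapply(seq_len(nSlices), function(i) {
    rasterizeSlice(endo, epi, scar, planes$origins[i, ], planes$normal,
                   spacing = spacing, sliceIndex = i - 1L,
                   minRegionPixels = minRegionPixels)
  })
  attr(masks, "sliceSpacing") <- planes$spacing
  attr(masks, "normal") <- planes$normal
  masks
}

#' Sample volume intensities under a slice-mask region
#'
#' Nearest-voxel sampling of the voxels intersected by the slice plane at
#' the masked pixels; samples are returned in row-major pixel order.
#'
#' @param volume an [ImageVolume-class].
#' @param mask a [SliceMask-class].
#' @param regionLabel 1 for (non-scar) myocardium, 2 for scar.
#' @return Numeric vector of intensities (possibly empty).
#' @export
extractRegionIntensities <- function(volume, mask, regionLabel) {
  px <- mask@pixels
  if (!length(px)) return(numeric(0))
  idx <- which(px == as.integer(regionLabel), arr.ind = TRUE)
  if (!nrow(idx)) return(numeric(0))
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]  # row-major
  uc <- mask@gridOffset[1] + (idx[, 1] - 1) * mask@pixelSpacing
  vc <- mask@gridOffset[2] + (idx[, 2] - 1) * mask@pixelSpacing
  pts <- sweep(outer(uc, mask@axisU) + outer(vc, mask@axisV), 2,
               mask@planeOrigin, "+")
  vox <- sweep(pts, 2, volume@origin)
  vox <- round(sweep(vox %*% volume@orientation, 2, volume@spacing, "/")) + 1
  d <- dim(volume@voxels)
  oob <- vox[, 1] < 1 | vox[, 1] > d[1] | vox[, 2] < 1 | vox[, 2] > d[2] |
    vox[, 3] < 1 | vox[, 3] > d[3]
  if (any(oob)) stop("extractRegionIntensities: mask maps outside the volume")
  volume@voxels[cbind(vox[, 1], vox[, 2], vox[, 3])]
}

#' Slice bookkeeping table
#'
#' @param masks list from [sliceStack()].
#' @return data.frame with slice_index, valid, myocardium_px, scar_px.
#' @export
sliceManifest <- function(masks) {
  do.call(rbind, lapply(masks, function(m) {
    data.frame(slice_index = m@sliceIndex, valid = m@valid,
               myocardium_px = sum(m@pixels == 1L),
               scar_px = sum(m@pixels == 2L))
  }))
}
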