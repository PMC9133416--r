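# Combined-energy image synthesis: rigid intensity-based registration of
# the 100 kV volume onto the 80 kV grid, then voxelwise convex weighting at
# the configured contribution levels (40/50/60%).

# trilinear sample of volume at world points; outside the field of view
# returns `fill`
sampleVolume <- function(volume, points, fill = -1024) {
  d <- dim(volume@voxels)
  rel <- sweep(points, 2, volume@origin) %*% volume@orientation
  ix <- rel[, 1] / volume@spacing[1] + 1
  iy <- rel[, 2] / volume@spacing[2] + 1
  iz <- rel[, 3] / volume@spacing[3] + 1
  x0 <- floor(ix); y0 <- floor(iy); z0 <- floor(iz)
  fx <- ix - x0; fy <- iy - y0; fz <- iz - z0
  ok <- x0 >= 1 & x0 + 1 <= d[1] & y0 >= 1 & y0 + 1 <= d[2] &
    z0 >= 1 & z0 + 1 <= d[3]
  out <- rep(fill, nrow(points))
  if (!any(ok)) return(out)
  x0 <- x0[ok]; y0 <- y0[ok]; z0 <- z0[ok]
  fx <- fx[ok]; fy <- fy[ok]; fz <- fz[ok]
  v <- volume@voxels
  g <- function(dx, dy, dz) v[cbind(x0 + dx, y0 + dy, z0 + dz)]
  out[ok] <-
    g(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
    g(1, 0, 0) * fx * (1 - fy) * (1 - fz) +
    g(0, 1, 0) * (1 - fx) * fy * (1 - fz) +
    g(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
    g(1, 1, 0) * fx * fy * (1 - fz) +
    g(1, 0, 1) * fx * (1 - fy) * fz +
    g(0, 1, 1) * (1 - fx) * fy * fz +
    g(1, 1, 1) * fx * fy * fz
  out
}

# world coordinates of every voxel centre (optionally strided)
voxelCentres <- function(volume, stride = 1L) {
  d <- dim(volume@voxels)
  xs <- seq(1L, d[1], by = stride); ys <- seq(1L, d[2], by = stride)
  zs <- seq(1L, d[3], by = stride)
  g <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  idx <- g
  rel <- sweep(g - 1, 2, volume@spacing, "*") %*% t(volume@orientation)
  list(points = sweep(rel, 2, volume@origin, "+"), index = idx)
}

eulerToRotation <- function(a) {
  rotationAboutAxis(c(0, 0, 1), a[3]) %*%
    rotationAboutAxis(c(0, 1, 0), a[2]) %*%
    rotationAboutAxis(c(1, 0, 0), a[1])
}

#' Rigid intensity-based volume registration
#'
#' Finds the rigid transform (rotation about the fixed volume's centre plus
#' translation) that minimises the mean squared intensity difference
#' between the fixed volume and the resampled moving volume, by
#' regular-step gradient descent with central-difference gradients and
#' step halving.  Voxels falling outside the moving field of view are
#' excluded from the metric.
#'
#' @param moving,fixed [ImageVolume-class] objects with overlapping fields
#'   of view.
#' @param stride voxel stride for metric evaluation (default 2; 1 uses
#'   every voxel).
#' @param maxIter maximum descent iterations.
#' @param initStep initial parameter step (mm and radian-equivalents).
#' @param minStep convergence threshold on the step length.
#' @param smoothSigma Gaussian presmoothing of both volumes before the
#'   metric is evaluated (voxels; 0 disables).  Smoothing suppresses
#'   noise-induced local minima of the MSE landscape.
#' @return A [RigidTransform-class] mapping moving-frame points onto the
#'   fixed frame, with attributes \code{converged}, \code{metric} (final
#'   MSE) and \code{overlap} (fraction of sampled voxels in the field of
#'   view).
#' @export
registerVolumes <- function(moving, fixed, stride = 2L, maxIter = 200L,
                            initStep = 2, minStep = 0.01,
                            smoothSigma = 1.5) {
  if (smoothSigma > 0) {
    moving <- ImageVolume(gaussianBlur3d(moving@voxels, smoothSigma),
                          moving@spacing, moving@origin, moving@orientation)
    fixed <- ImageVolume(gaussianBlur3d(fixed@voxels, smoothSigma),
                         fixed@spacing, fixed@origin, fixed@orientation)
  }
  vc <- voxelCentres(fixed, stride)
  pts <- vc$points
  fvals <- fixed@voxels[vc$index]
  centre <- colMeans(pts)
  # parameters: 3 rotations (rad) about the centre, 3 translations (mm);
  # rotations scaled so one unit step moves peripheral voxels ~comparably
  evalMetric <- function(par) {
    R <- eulerToRotation(par[1:3])
    moved <- sweep(sweep(pts, 2, centre) %*% t(R), 2, centre + par[4:6], "+")
    mv <- sampleVolume(moving, moved, fill = NA)
    ok <- !is.na(mv)
    if (sum(ok) < 0.05 * length(mv)) return(list(mse = Inf, overlap = 0))
    list(mse = mean((mv[ok] - fvals[ok])^2), overlap = mean(ok))
  }
  par <- rep(0, 6)
  cur <- evalMetric(par)
  step <- initStep
  scales <- c(rep(0.02, 3), rep(1, 3))  # rad vs mm per unit step
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    if (!is.finite(cur$mse)) break  # no usable overlap; report non-converged
    grad <- numeric(6)
    h <- scales * step * 0.5
    for (k in 1:6) {
      pp <- par; pp[k] <- pp[k] + h[k]
      pm <- par; pm[k] <- pm[k] - h[k]
      grad[k] <- (evalMetric(pp)$mse - evalMetric(pm)$mse) / (2 * h[k])
    }
    gn <- sqrt(sum((grad * scales)^2))
    if (!is.finite(gn)) break
    if (gn == 0) { converged <- TRUE; break }
    cand <- par - scales^2 * grad / gn * step
    new <- evalMetric(cand)
    if (new$mse < cur$mse) {
      par <- cand; cur <- new
    } else {
      step <- step / 2
      if (step < minStep) { converged <- TRUE; break }
    }
  }
  R <- eulerToRotation(par[1:3])
  # x -> R (x - c) + c + t, written as rotation + combined translation
  out <- RigidTransform(R, as.numeric(centre + par[4:6] - R %*% centre))
  attr(out, "converged") <- converged && is.finite(cur$mse)
  attr(out, "metric") <- cur$mse
  attr(out, "overlap") <- cur$overlap
  out
}

#' Resample a volume onto a reference grid
#'
#' Trilinear interpolation of \code{volume} at the voxel centres of
#' \code{reference}, after mapping them through \code{transform} (fixed
#' frame to moving frame sampling uses the inverse of a moving-to-fixed
#' transform; pass the transform returned by [registerVolumes()]).
#'
#' @param volume moving [ImageVolume-class].
#' @param reference [ImageVolume-class] providing the output grid.
#' @param transform [RigidTransform-class] mapping moving to fixed
#'   (identity by default).
#' @param fill value for out-of-field voxels (default -1024 HU).
#' @return An [ImageVolume-class] on the reference grid.
#' @export
resampleVolume <- function(volume, reference, transform = RigidTransform(),
                           fill = -1024) {
  vc <- voxelCentres(reference, 1L)
  inv <- invertTransform(transform)
  pts <- transformPoints(vc$points, inv)
  vals <- sampleVolume(volume, pts, fill = fill)
  out <- reference
  out@voxels <- array(vals, dim(reference@voxels))
  out
}

#' Weighted combined-energy image
#'
#' Voxelwise convex combination w * high + (1 - w) * low on the low-energy
#' (80 kV) grid; the stated percentage contribution of the high-energy
#' image implies convex weights summing to one (a raw sum would double the
#' HU scale).  Masks from the low-energy analysis apply unchanged.
#'
#' @param low low-energy [ImageVolume-class] (defines the grid).
#' @param highRegistered high-energy volume already resampled onto
#'   \code{low}'s grid.
#' @param w high-energy contribution in (0, 1).
#' @return An [ImageVolume-class] on the low-energy grid.
#' @export
combineEnergies <- function(low, highRegistered, w) {
  stopifnot(w > 0, w < 1)
  if (!all(dim(low@voxels) == dim(highRegistered@voxels)) ||
      any(abs(low@spacing - highRegistered@spacing) > 1e-9))
    stop("combineEnergies: volumes are not on the same grid")
  out <- low
  out@voxels <- w * highRegistered@voxels + (1 - w) * low@voxels
  out
}
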