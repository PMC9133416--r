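# Three-step rigid registration of the MRI left ventricle onto the CT left
# ventricle: (1) major-axis alignment, (2) rotation about the long axis from
# the right-ventricular insertion points, (3) point-to-point ICP refinement
# on the whole endocardium.  The composed transform is then applied to the
# MRI scar mesh to carry the scar label into the CT frame.

#' Principal (long) axis of a mesh
#'
#' Dominant eigendirection of the vertex covariance, sign-fixed to point
#' from the base toward the apex.  The apex end is identified as the axial
#' end with the smaller mean radial spread about the axis (the tapered end
#' of the ventricle), so no landmark is needed.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param gapTol minimum relative eigenvalue gap between the first and
#'   second principal components; below it the vertex cloud is considered
#'   near-isotropic and an error is raised.
#' @return Unit length-3 vector.
#' @export
principalAxis <- function(mesh, gapTol = 1e-6) {
  v <- mesh@vertices
  if (nrow(v) < 4) stop("principalAxis: mesh needs >= 4 vertices")
  e <- eigen(stats::cov(v), symmetric = TRUE)
  if (e$values[1] < (1 + gapTol) * e$values[2])
    stop("principalAxis: degenerate (near-isotropic) vertex cloud")
  axis <- e$vectors[, 1]
  ctr <- colMeans(v)
  s <- as.numeric(sweep(v, 2, ctr) %*% axis)      # axial coordinate
  radial <- sqrt(rowSums((sweep(v, 2, ctr) - outer(s, axis))^2))
  med <- stats::median(s)
  # apex = tapered end: smaller mean radius among vertices past the median
  spreadPos <- mean(radial[s > med])
  spreadNeg <- mean(radial[s < med])
  if (spreadPos > spreadNeg) axis <- -axis
  axis / sqrt(sum(axis^2))
}

#' Step 1: align the major axes of two meshes
#'
#' Minimal-angle rotation mapping the moving mesh's long axis onto the
#' fixed mesh's, plus the translation aligning vertex centroids.
#'
#' @param moving,fixed [SurfaceMesh-class] objects.
#' @return A [RigidTransform-class].
#' @export
alignMajorAxes <- function(moving, fixed) {
  aM <- principalAxis(moving)
  aF <- principalAxis(fixed)
  R <- rotationBetween(aM, aF)
  cM <- colMeans(moving@vertices)
  cF <- colMeans(fixed@vertices)
  RigidTransform(R, as.numeric(cF - R %*% cM))
}

#' Step 2: rotate about the long axis from the RV insertion points
#'
#' Pure rotation about \code{longAxis} through the fixed mesh centroid that
#' minimises the summed squared distance between corresponding RV insertion
#' landmarks projected onto the plane orthogonal to the axis (closed-form
#' 2D Procrustes angle).
#'
#' @param moving,fixed [SurfaceMesh-class] objects carrying both
#'   \code{rv_insertion_anterior} and \code{rv_insertion_inferior} landmarks.
#' @param longAxis unit length-3 vector (the shared long axis).
#' @return A [RigidTransform-class] (rotation about the axis).
#' @export
alignRvInsertions <- function(moving, fixed, longAxis) {
  need <- c("rv_insertion_anterior", "rv_insertion_inferior")
  for (nm in need) {
    if (is.null(moving@landmarks[[nm]]))
      stop("alignRvInsertions: moving mesh missing landmark ", nm)
    if (is.null(fixed@landmarks[[nm]]))
      stop("alignRvInsertions: fixed mesh missing landmark ", nm)
  }
  a <- longAxis / sqrt(sum(longAxis^2))
  ctr <- colMeans(fixed@vertices)
  # orthonormal in-plane basis
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * a) * a; u <- u / sqrt(sum(u^2))
  w <- c(a[2] * u[3] - a[3] * u[2], a[3] * u[1] - a[1] * u[3],
         a[1] * u[2] - a[2] * u[1])
  proj <- function(p) {
    d <- p - ctr
    c(sum(d * u), sum(d * w))
  }
  num <- 0; den <- 0
  for (nm in need) {
    pM <- proj(moving@landmarks[[nm]])
    pF <- proj(fixed@landmarks[[nm]])
    if (sqrt(sum(pM^2)) < 1e-9 || sqrt(sum(pF^2)) < 1e-9)
      stop("alignRvInsertions: landmark on the long axis (zero projected radius)")
    num <- num + (pM[1] * pF[2] - pM[2] * pF[1])
    den <- den + (pM[1] * pF[1] + pM[2] * pF[2])
  }
  theta <- atan2(num, den)
  rotationAboutPoint(a, theta, ctr)
}

# closed-form least-squares rigid fit (Kabsch) of moving -> fixed point sets
kabsch <- function(moving, fixed) {
  cM <- colMeans(moving); cF <- colMeans(fixed)
  H <- crossprod(sweep(moving, 2, cM), sweep(fixed, 2, cF))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  RigidTransform(R, as.numeric(cF - R %*% cM))
}

# nearest fixed-vertex index for each moving point (blocked brute force)
nearestVertex <- function(points, target) {
  t2 <- rowSums(target^2)
  n <- nrow(points)
  idx <- integer(n)
  block <- max(1L, as.integer(2e6 / nrow(target)))
  for (s in seq(1L, n, by = block)) {
    e <- min(n, s + block - 1L)
    d <- outer(rowSums(points[s:e, , drop = FALSE]^2), t2, "+") -
      2 * points[s:e, , drop = FALSE] %*% t(target)
    idx[s:e] <- max.col(-d, ties.method = "first")
  }
  idx
}

#' Step 3: point-to-point iterative closest point registration
#'
#' Alternates nearest-vertex correspondence with the closed-form SVD
#' (Kabsch) rigid update.  The objective is the RMS correspondence
#' distance, which the update provably does not increase; iteration stops
#' when the improvement drops below \code{tol} or \code{maxIter} is
#' reached.
#'
#' @param moving,fixed [SurfaceMesh-class] objects.
#' @param init [RigidTransform-class] initial transform (already applied
#'   before the first correspondence search and included in the result).
#' @param maxIter maximum iterations (default 100).
#' @param tol convergence tolerance on the RMS distance improvement (mm,
#'   default 1e-4).
#' @return A [RigidTransform-class] with attributes \code{converged}
#'   (logical), \code{rms} (final RMS distance, mm) and \code{history}
#'   (per-iteration RMS).
#' @export
icp <- function(moving, fixed, init = RigidTransform(), maxIter = 100L,
                tol = 1e-4) {
  stopifnot(maxIter >= 1L, tol > 0)
  if (!nrow(moving@vertices) || !nrow(fixed@vertices))
    stop("icp: empty mesh")
  Vf <- fixed@vertices
  cur <- init
  pts <- transformPoints(moving@vertices, cur)
  history <- numeric(0)
  rmsPrev <- Inf
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    corr <- Vf[nearestVertex(pts, Vf), , drop = FALSE]
    upd <- kabsch(pts, corr)
    cur <- composeTransforms(upd, cur)
    pts <- transformPoints(moving@vertices, cur)
    corr2 <- Vf[nearestVertex(pts, Vf), , drop = FALSE]
    rms <- sqrt(mean(rowSums((pts - corr2)^2)))
    history <- c(history, rms)
    if (rmsPrev - rms < tol) { converged <- TRUE; break }
    rmsPrev <- rms
  }
  attr(cur, "converged") <- converged
  attr(cur, "rms") <- history[length(history)]
  attr(cur, "history") <- history
  cur
}

#' Full three-step LV registration
#'
#' Composition \code{icp} after \code{alignRvInsertions} after
#' \code{alignMajorAxes}: the major axes are aligned first, the RV
#' insertion points then fix the rotation about the long axis, and a final
#' whole-endocardium ICP fine-tunes the result.  The returned transform
#' maps the moving (MRI) frame into the fixed (CT) frame.
#'
#' @param movingEndo,fixedEndo endocardial [SurfaceMesh-class] objects, both
#'   carrying the two RV insertion landmarks.
#' @param maxIter,tol passed to [icp()].
#' @return A [RigidTransform-class] with the [icp()] diagnostic attributes.
#' @export
registerLV <- function(movingEndo, fixedEndo, maxIter = 100L, tol = 1e-4) {
  t1 <- tryCatch(alignMajorAxes(movingEndo, fixedEndo),
                 error = function(e) stop("major-axis step: ",
                                          conditionMessage(e), call. = FALSE))
  moved1 <- applyTransform(movingEndo, t1)
  axis <- principalAxis(fixedEndo)
  t2 <- tryCatch(alignRvInsertions(moved1, fixedEndo, axis),
                 error = function(e) stop("rv-insertion step: ",
                                          conditionMessage(e), call. = FALSE))
  init <- composeTransforms(t2, t1)
  tryCatch(icp(movingEndo, fixedEndo, init = init, maxIter = maxIter,
               tol = tol),
           error = function(e) stop("icp step: ", conditionMessage(e),
                                    call. = FALSE))
}

#' Automatic registration quality check
#'
#' Replaces by-eye inspection: verifies that after registration the apex
#' landmarks and base centroids of the two meshes are within stated
#' distances.
#'
#' @param registered moving endocardium after applying the transform.
#' @param fixed fixed endocardium.
#' @param apexTol,baseTol distance thresholds (mm).
#' @return Logical; TRUE when both checks pass (missing apex landmarks fall
#'   back to the base-centroid check only).
#' @export
registrationQC <- function(registered, fixed, apexTol = 5, baseTol = 5) {
  ok <- TRUE
  aR <- registered@landmarks[["apex"]]
  aF <- fixed@landmarks[["apex"]]
  if (!is.null(aR) && !is.null(aF))
    ok <- ok && sqrt(sum((aR - aF)^2)) <= apexTol
  axF <- principalAxis(fixed)
  baseC <- function(mesh, ax) {
    v <- mesh@vertices
    s <- as.numeric(sweep(v, 2, colMeans(v)) %*% ax)
    colMeans(v[s < stats::quantile(s, 0.1), , drop = FALSE])
  }
  ok && sqrt(sum((baseC(registered, axF) - baseC(fixed, axF))^2)) <= baseTol
}
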