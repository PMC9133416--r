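# Rigid transform algebra: composition, inversion, rotation constructors.

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying \code{first}, then
#' \code{second}: x -> R2 (R1 x + t1) + t2.
#'
#' @param second,first [RigidTransform-class] objects.
#' @return A [RigidTransform-class].
#' @export
composeTransforms <- function(second, first) {
  RigidTransform(second@rotation %*% first@rotation,
                 as.numeric(second@rotation %*% first@translation) +
                   second@translation)
}

#' Invert a rigid transform
#'
#' @param t a [RigidTransform-class].
#' @return The inverse transform x -> R' (x - t).
#' @export
invertTransform <- function(t) {
  Rt <- t(t@rotation)
  RigidTransform(Rt, as.numeric(-Rt %*% t@translation))
}

#' Rotation about an arbitrary axis
#'
#' Rodrigues rotation matrix for a given axis and angle.
#'
#' @param axis length-3 vector (normalised internally).
#' @param angle rotation angle in radians.
#' @return 3 x 3 rotation matrix.
#' @export
rotationAboutAxis <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2],
                -a[3], 0, a[1],
                a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Rotation angle of a rotation matrix
#'
#' @param R 3 x 3 rotation matrix.
#' @return Rotation angle in radians, in [0, pi].
#' @export
rotationAngle <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
}

# minimal-angle rotation taking unit vector a onto unit vector b
rotationBetween <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  c_ <- sum(a * b)
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # anti-parallel: rotate pi about a deterministic axis orthogonal to a
    ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- c(a[2] * ref[3] - a[3] * ref[2],
            a[3] * ref[1] - a[1] * ref[3],
            a[1] * ref[2] - a[2] * ref[1])
    return(rotationAboutAxis(ax, pi))
  }
  rotationAboutAxis(v, atan2(s, c_))
}

# rotation about `axis` through fixed point `center`, as a RigidTransform
rotationAboutPoint <- function(axis, angle, center) {
  R <- rotationAboutAxis(axis, angle)
  RigidTransform(R, as.numeric(center - R %*% center))
}

#' Apply a rigid transform to points
#'
#' @param points n x 3 matrix of points.
#' @param t a [RigidTransform-class].
#' @return n x 3 matrix of transformed points.
#' @export
transformPoints <- function(points, t) {
  points <- rbind(points)  # tolerate a single point as a vector
  sweep(points %*% t(t@rotation), 2, t@translation, "+")
}

#' Apply a rigid transform to a mesh
#'
#' Maps every vertex and landmark v -> R v + t; faces and landmark names
#' are preserved.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param t a [RigidTransform-class].
#' @return The transformed [SurfaceMesh-class].
#' @export
applyTransform <- function(mesh, t) {
  lm <- lapply(mesh@landmarks, function(p) as.numeric(transformPoints(p, t)))
  SurfaceMesh(transformPoints(mesh@vertices, t), mesh@faces, lm)
}

#' Serialize a rigid transform to JSON
#'
#' Row-major 3 x 3 rotation plus translation, the sidecar format used for
#' per-case ground-truth and registration outputs.
#'
#' @param t a [RigidTransform-class].
#' @param path file to write.
#' @return \code{path}, invisibly.
#' @export
writeTransformJSON <- function(t, path) {
  jsonlite::write_json(list(rotation = as.numeric(t(t@rotation)),
                            translation = t@translation),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a rigid transform from JSON
#'
#' @param path file written by [writeTransformJSON()].
#' @return A [RigidTransform-class].
#' @export
readTransformJSON <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  RigidTransform(matrix(x$rotation, 3, 3, byrow = TRUE), x$translation)
}
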