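#' @import methods
NULL

#' Triangulated cardiac surface mesh
#'
#' Container for a triangulated surface of a left-ventricular structure
#' (endocardium, epicardium or scar) with optional named anatomical
#' landmarks.  Coordinates are in millimetres.
#'
#' @slot vertices numeric matrix, n x 3, one row per vertex (mm).
#' @slot faces integer matrix, m x 3, 1-based vertex indices per triangle.
#' @slot landmarks named list of length-3 numeric vectors; recognised names
#'   are \code{rv_insertion_anterior}, \code{rv_insertion_inferior},
#'   \code{apex}.
#'
#' @seealso [SurfaceMesh()], [applyTransform()], [principalAxis()]
#' @exportClass SurfaceMesh
setClass("SurfaceMesh",
  representation(vertices = "matrix", faces = "matrix", landmarks = "list"),
  prototype(vertices = matrix(numeric(0), 0, 3),
            faces = matrix(integer(0), 0, 3),
            landmarks = list()))

setValidity("SurfaceMesh", function(object) {
  v <- object@vertices; f <- object@faces
  if (ncol(v) != 3) return("vertices must have 3 columns")
  if (ncol(f) != 3) return("faces must have 3 columns")
  if (nrow(v) && !all(is.finite(v))) return("vertex coordinates must be finite")
  if (nrow(f)) {
    if (min(f) < 1 || max(f) > nrow(v))
      return("face indices out of vertex range")
  }
  lm <- object@landmarks
  if (length(lm)) {
    if (is.null(names(lm)) || any(names(lm) == ""))
      return("landmarks must be named")
    bad <- !vapply(lm, function(p) is.numeric(p) && length(p) == 3 &&
                     all(is.finite(p)), logical(1))
    if (any(bad)) return("each landmark must be a finite length-3 numeric")
  }
  TRUE
})

#' Construct a SurfaceMesh
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param faces m x 3 matrix of 1-based vertex indices.
#' @param landmarks named list of length-3 points, e.g.
#'   \code{list(rv_insertion_anterior = c(x, y, z))}.
#' @return A [SurfaceMesh-class] object.
#' @export
SurfaceMesh <- function(vertices, faces = matrix(integer(0), 0, 3),
                        landmarks = list()) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  new("SurfaceMesh", vertices = vertices, faces = faces,
      landmarks = landmarks)
}

#' Rigid-body transform
#'
#' A proper rigid transform v -> R v + t with \code{R} a rotation matrix
#' (orthonormal, det +1) and \code{t} a translation in millimetres.
#'
#' @slot rotation 3 x 3 rotation matrix.
#' @slot translation length-3 numeric (mm).
#' @seealso [RigidTransform()], [composeTransforms()], [invertTransform()]
#' @exportClass RigidTransform
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"),
  prototype(rotation = diag(3), translation = c(0, 0, 0)))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3, 3))) return("rotation must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    return("rotation must be orthonormal (R'R = I within 1e-8)")
  if (det(R) < 0) return("rotation must be proper (det +1)")
  if (length(object@translation) != 3) return("translation must be length 3")
  TRUE
})

#' Construct a RigidTransform
#'
#' @param rotation 3 x 3 rotation matrix (orthonormal, det +1).
#' @param translation length-3 numeric translation (mm).
#' @return A [RigidTransform-class] object.
#' @export
RigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation))
}

#' 3D scalar image volume
#'
#' CT-like voxel grid with spacing, origin and axis orientation.  The voxel
#' at array index (i, j, k) (1-based) is centred at
#' \code{origin + orientation \%*\% ((c(i,j,k) - 1) * spacing)}.
#'
#' @slot voxels 3D numeric array (HU).
#' @slot spacing length-3 positive numeric (mm).
#' @slot origin length-3 numeric, world position of the first voxel centre.
#' @slot orientation 3 x 3 orthonormal direction matrix.
#' @exportClass ImageVolume
setClass("ImageVolume",
  representation(voxels = "array", spacing = "numeric", origin = "numeric",
                 orientation = "matrix"),
  prototype(voxels = array(0, c(1, 1, 1)), spacing = c(1, 1, 1),
            origin = c(0, 0, 0), orientation = diag(3)))

setValidity("ImageVolume", function(object) {
  if (length(dim(object@voxels)) != 3) return("voxels must be a 3D array")
  if (length(object@spacing) != 3 || any(object@spacing <= 0))
    return("spacing must be 3 positive values")
  if (length(object@origin) != 3) return("origin must be length 3")
  o <- object@orientation
  if (!all(dim(o) == c(3, 3)) || max(abs(crossprod(o) - diag(3))) > 1e-8)
    return("orientation must be a 3x3 orthonormal matrix")
  TRUE
})

#' Construct an ImageVolume
#'
#' @param voxels 3D numeric array of intensities (HU).
#' @param spacing length-3 voxel spacing (mm).
#' @param origin world position of the first voxel centre.
#' @param orientation 3 x 3 direction matrix (default identity).
#' @return An [ImageVolume-class] object.
#' @export
ImageVolume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        orientation = diag(3)) {
  new("ImageVolume", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin), orientation = orientation)
}

#' One short-axis slice's label mask
#'
#' A 2D label grid for one short-axis plane: 0 background, 1 myocardium,
#' 2 scar (scar pixels are a subset of the myocardial ring, projected
#' transmurally).  The plane is parameterised by an origin, a unit normal
#' (the long axis) and two in-plane unit axes \code{u}, \code{v}; pixel
#' (r, c) (1-based, row-major) is centred at
#' \code{origin + (r-1)*spacing*u + (c-1)*spacing*v} offset by the stored
#' grid offset.
#'
#' @slot sliceIndex 0-based slice index.
#' @slot planeOrigin length-3 numeric, plane origin point.
#' @slot planeNormal length-3 unit vector (long axis direction).
#' @slot axisU,axisV in-plane orthonormal unit vectors.
#' @slot gridOffset length-2 numeric: in-plane (u, v) coordinate of pixel (1, 1).
#' @slot pixels integer matrix of labels in \{0, 1, 2\}.
#' @slot pixelSpacing positive scalar (mm).
#' @slot valid logical; FALSE when the analysed regions are below the
#'   minimum pixel count.
#' @slot hasCavity logical; TRUE when the plane still cuts the endocardial
#'   cavity (FALSE over the apical cap).
#' @exportClass SliceMask
setClass("SliceMask",
  representation(sliceIndex = "integer", planeOrigin = "numeric",
                 planeNormal = "numeric", axisU = "numeric", axisV = "numeric",
                 gridOffset = "numeric", pixels = "matrix",
                 pixelSpacing = "numeric", valid = "logical",
                 hasCavity = "logical"),
  prototype(hasCavity = TRUE))

setValidity("SliceMask", function(object) {
  if (object@pixelSpacing <= 0) return("pixelSpacing must be > 0")
  px <- object@pixels
  if (length(px) && !all(px %in% 0:2))
    return("pixel labels must be 0 (background), 1 (myocardium) or 2 (scar)")
  for (nm in c("planeNormal", "axisU", "axisV")) {
    a <- slot(object, nm)
    if (abs(sqrt(sum(a^2)) - 1) > 1e-6) return(paste(nm, "must be unit length"))
  }
  TRUE
})

#' Synthetic-cohort generation parameters
#'
#' Parameters of the left-ventricle phantom generator.  The LV is a
#' truncated prolate half-ellipsoid shell with a contiguous transmural
#' wedge of scar; two tube-voltage channels differ by a contrast scale and
#' a noise standard deviation.
#'
#' @slot nPatients positive integer, cohort size.
#' @slot endoRadius,epiRadius equatorial radii (mm), epi > endo.
#' @slot lvLength base-to-apex length of the endocardial cavity (mm).
#' @slot scarFractionRange length-2 numeric in [0, 1]: per-patient scar
#'   volume fraction is drawn uniformly from this interval.
#' @slot scarMeanShift intensity added inside scar (HU, at unit contrast).
#' @slot scarTextureSmoothing spatial correlation length of scar noise (mm);
#'   larger values give a more homogeneous scar texture.
#' @slot scarNoiseScale scar noise sd as a fraction of the energy's
#'   myocardial noise sd (scar texture is smoother and less noisy).
#' @slot patientBaselineSd between-patient sd of the tissue enhancement
#'   baseline (HU): each case's tissue intensities share one random offset,
#'   emulating patient-specific contrast kinetics.
#' @slot energies character vector of energy labels to simulate.
#' @slot noiseSdPerEnergy named numeric, HU noise sd per energy label.
#' @slot contrastPerEnergy named numeric, contrast scale per energy label.
#' @slot misalignmentMaxRotation max rotation of the hidden MRI-to-CT
#'   misalignment (degrees).
#' @slot misalignmentMaxTranslation max translation of the misalignment (mm).
#' @slot vertexNoiseSd isotropic Gaussian noise on MRI mesh vertices (mm).
#' @slot voxelSpacing isotropic voxel spacing of the simulated volumes (mm).
#' @slot seed integer master seed.
#' @exportClass PhantomParams
setClass("PhantomParams",
  representation(nPatients = "integer", endoRadius = "numeric",
                 epiRadius = "numeric", lvLength = "numeric",
                 scarFractionRange = "numeric", scarMeanShift = "numeric",
                 scarTextureSmoothing = "numeric", scarNoiseScale = "numeric",
                 patientBaselineSd = "numeric", energies = "character",
                 noiseSdPerEnergy = "numeric", contrastPerEnergy = "numeric",
                 misalignmentMaxRotation = "numeric",
                 misalignmentMaxTranslation = "numeric",
                 vertexNoiseSd = "numeric", voxelSpacing = "numeric",
                 seed = "integer"))

setValidity("PhantomParams", function(object) {
  if (object@nPatients < 1L) return("nPatients must be >= 1")
  if (object@endoRadius <= 0) return("endoRadius must be > 0")
  if (object@epiRadius <= object@endoRadius)
    return("epiRadius must exceed endoRadius")
  if (object@lvLength <= 0) return("lvLength must be > 0")
  r <- object@scarFractionRange
  if (length(r) != 2 || any(r < 0) || any(r > 1) || r[1] > r[2])
    return("scarFractionRange must be an interval within [0, 1]")
  if (object@scarTextureSmoothing < 0)
    return("scarTextureSmoothing must be >= 0")
  if (object@scarNoiseScale < 0 || object@scarNoiseScale > 1)
    return("scarNoiseScale must be in [0, 1]")
  if (object@patientBaselineSd < 0)
    return("patientBaselineSd must be >= 0")
  if (any(object@noiseSdPerEnergy < 0))
    return("noiseSdPerEnergy entries must be >= 0")
  if (!all(object@energies %in% names(object@noiseSdPerEnergy)))
    return("every energy needs a noiseSdPerEnergy entry")
  if (!all(object@energies %in% names(object@contrastPerEnergy)))
    return("every energy needs a contrastPerEnergy entry")
  if (object@misalignmentMaxRotation < 0 ||
      object@misalignmentMaxTranslation < 0)
    return("misalignment bounds must be >= 0")
  if (object@vertexNoiseSd < 0) return("vertexNoiseSd must be >= 0")
  if (object@voxelSpacing <= 0) return("voxelSpacing must be > 0")
  TRUE
})

#' One synthetic patient case
#'
#' Holds the per-patient inputs the pipeline consumes (meshes in the CT and
#' MRI frames, RV insertion landmarks, dual-energy volumes) plus the hidden
#' ground truth (true misalignment, true scar label grid, true scar
#' fraction) used only by tests and evaluation.
#'
#' @slot patientId character identifier.
#' @slot ctEndo,ctEpi CT-frame endo/epicardial meshes.
#' @slot mriEndo,mriEpi MRI-frame meshes (misaligned + vertex noise).
#' @slot scarMeshMri scar surface mesh in the MRI frame.
#' @slot trueMisalignment [RigidTransform-class] mapping the MRI frame onto
#'   the CT frame (ground truth; applying it to MRI vertices reproduces the
#'   CT vertices up to vertex noise).
#' @slot volumes named list of [ImageVolume-class], one per energy label.
#' @slot trueScarLabel [ImageVolume-class] binary grid aligned with the CT
#'   volumes (1 = scar).
#' @slot trueScarFraction scar fraction of myocardial volume actually drawn.
#' @slot scarEmpty logical, TRUE when the case carries no scar.
#' @exportClass PhantomCase
setClass("PhantomCase",
  representation(patientId = "character", ctEndo = "SurfaceMesh",
                 ctEpi = "SurfaceMesh", mriEndo = "SurfaceMesh",
                 mriEpi = "SurfaceMesh", scarMeshMri = "SurfaceMesh",
                 trueMisalignment = "RigidTransform", volumes = "list",
                 trueScarLabel = "ImageVolume", trueScarFraction = "numeric",
                 scarEmpty = "logical"))

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh: %d vertices, %d faces", nrow(object@vertices),
              nrow(object@faces)))
  if (length(object@landmarks))
    cat(sprintf(", landmarks: %s", paste(names(object@landmarks),
                                         collapse = ", ")))
  cat("\n")
})

setMethod("show", "RigidTransform", function(object) {
  ang <- rotationAngle(object@rotation) * 180 / pi
  cat(sprintf("RigidTransform: rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang, object@translation[1], object@translation[2],
              object@translation[3]))
})

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ImageVolume: %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
})

setMethod("show", "SliceMask", function(object) {
  cat(sprintf("SliceMask %d: %d myocardium px, %d scar px, valid=%s\n",
              object@sliceIndex, sum(object@pixels == 1L),
              sum(object@pixels == 2L), object@valid))
})

setMethod("show", "PhantomCase", function(object) {
  cat(sprintf("PhantomCase %s: scar fraction %.3f%s, energies: %s\n",
              object@patientId, object@trueScarFraction,
              if (object@scarEmpty) " (no scar)" else "",
              paste(names(object@volumes), collapse = ", ")))
})

# ---- accessors ----

#' Mesh vertices
#' @param x a [SurfaceMesh-class].
#' @return n x 3 numeric matrix.
#' @export
meshVertices <- function(x) x@vertices

#' Mesh faces
#' @param x a [SurfaceMesh-class].
#' @return m x 3 integer matrix of 1-based indices.
#' @export
meshFaces <- function(x) x@faces

#' Mesh landmarks
#' @param x a [SurfaceMesh-class].
#' @return named list of length-3 points.
#' @export
meshLandmarks <- function(x) x@landmarks

#' Voxel array of a volume
#' @param x an [ImageVolume-class].
#' @return 3D numeric array.
#' @export
volumeVoxels <- function(x) x@voxels

#' Voxel spacing of a volume
#' @param x an [ImageVolume-class].
#' @return length-3 numeric (mm).
#' @export
volumeSpacing <- function(x) x@spacing

#' Label pixels of a slice mask
#' @param x a [SliceMask-class].
#' @return integer matrix with values 0/1/2.
#' @export
maskPixels <- function(x) x@pixels

#' Validity flag of a slice mask
#' @param x a [SliceMask-class].
#' @return logical scalar.
#' @export
maskValid <- function(x) x@valid
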