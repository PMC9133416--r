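# File interchange: ASCII PLY meshes, NIfTI volumes, CSV feature tables.

#' Write a mesh as ASCII PLY
#'
#' Landmarks, if any, go to a JSON sidecar next to the PLY
#' (\code{<path>.landmarks.json}).
#'
#' @param mesh a [SurfaceMesh-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writePLY <- function(mesh, path) {
  v <- mesh@vertices; f <- mesh@faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  if (nrow(v))
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  if (nrow(f))
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
               con)
  if (length(mesh@landmarks))
    jsonlite::write_json(mesh@landmarks, paste0(path, ".landmarks.json"),
                         auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read an ASCII PLY mesh
#'
#' Reads vertex coordinates and triangular faces; a
#' \code{<path>.landmarks.json} sidecar, when present, is loaded as
#' landmarks.
#'
#' @param path PLY file written by [writePLY()] or any ASCII PLY with
#'   x/y/z vertex properties and triangular faces.
#' @return A [SurfaceMesh-class].
#' @export
readPLY <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply" || !grepl("ascii", lines[2]))
    stop("readPLY: not an ASCII PLY file")
  endH <- match("end_header", lines)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)[1]))
  if (is.na(nf)) nf <- 0L
  v <- matrix(numeric(0), 0, 3)
  if (nv > 0) {
    v <- matrix(scan(text = lines[(endH + 1):(endH + nv)], quiet = TRUE),
                ncol = 3, byrow = TRUE)[, 1:3, drop = FALSE]
  }
  f <- matrix(integer(0), 0, 3)
  if (nf > 0) {
    raw <- matrix(scan(text = lines[(endH + nv + 1):(endH + nv + nf)],
                       quiet = TRUE), ncol = 4, byrow = TRUE)
    f <- raw[, 2:4, drop = FALSE] + 1L
  }
  lmPath <- paste0(path, ".landmarks.json")
  lm <- if (file.exists(lmPath))
    lapply(jsonlite::read_json(lmPath, simplifyVector = TRUE), as.numeric)
  else list()
  SurfaceMesh(v, f, lm)
}

#' Write an ImageVolume as NIfTI-1
#'
#' @param volume an [ImageVolume-class].
#' @param path output file (.nii or .nii.gz).
#' @return \code{path}, invisibly.
#' @export
writeVolumeNIfTI <- function(volume, path) {
  img <- RNifti::asNifti(volume@voxels, pixdim = volume@spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI file as an ImageVolume
#'
#' @param path NIfTI file.
#' @return An [ImageVolume-class] (origin from the sform when available).
#' @export
readVolumeNIfTI <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- attr(img, "pixdim")
  if (is.null(sp)) sp <- RNifti::pixdim(img)
  ImageVolume(array(as.numeric(img), dim(img)), spacing = sp[1:3])
}

#' Write a tidy feature table as CSV
#'
#' @param features data.frame, one row per (patient, energy, slice, region).
#' @param path output CSV.
#' @return \code{path}, invisibly.
#' @export
writeFeatureTable <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [writeFeatureTable()]
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
readFeatureTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
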