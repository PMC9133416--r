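# Gray-level texture matrix builders (2D, masked regions).  All builders
# take a discretized region: a list with integer matrix `gray` (levels in
# 1..nLevels, NA outside the mask), logical matrix `mask`, and `nLevels`.
# Conventions: GLCM symmetrized and summed over offsets; GLRLM summed over
# directions; GLDM/GLSZM/NGTDM use 8-connectivity / 8-neighbourhoods.

#' Discretize a masked intensity image
#'
#' Fixed-bin-width quantization anchored at the masked minimum:
#' level = floor((x - min) / binWidth) + 1.
#'
#' @param intensities numeric matrix (or vector) of intensities.
#' @param mask logical matrix (or vector) of the same shape; when missing,
#'   all finite pixels are masked.
#' @param binWidth positive bin width in intensity units (HU).
#' @return A list of class \code{DiscretizedRegion}: \code{gray} (integer,
#'   NA outside mask), \code{mask}, \code{nLevels}, \code{binEdges}.
#' @export
discretize <- function(intensities, mask = NULL, binWidth = 5) {
  stopifnot(binWidth > 0)
  x <- as.matrix(intensities)
  if (is.null(mask)) mask <- is.finite(x)
  mask <- as.matrix(mask)
  stopifnot(all(dim(mask) == dim(x)))
  if (!any(mask)) stop("discretize: empty mask")
  lo <- min(x[mask])
  gray <- matrix(NA_integer_, nrow(x), ncol(x))
  gray[mask] <- as.integer(floor((x[mask] - lo) / binWidth)) + 1L
  ng <- max(gray[mask])
  structure(list(gray = gray, mask = mask, nLevels = ng,
                 binEdges = lo + binWidth * (0:ng)),
            class = "DiscretizedRegion")
}

# the 8 chessboard neighbour offsets (row, col)
NEIGH8 <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

# pair up each masked pixel with its in-bounds masked neighbour at (dr, dc);
# returns a 2-column matrix of gray levels (centre, neighbour)
shiftPairs <- function(d, dr, dc) {
  g <- d$gray
  nr <- nrow(g); nc <- ncol(g)
  if (max(1, 1 - dr) > min(nr, nr - dr) || max(1, 1 - dc) > min(nc, nc - dc))
    return(matrix(integer(0), 0, 2))
  r1 <- max(1, 1 - dr):min(nr, nr - dr)
  c1 <- max(1, 1 - dc):min(nc, nc - dc)
  a <- g[r1, c1, drop = FALSE]
  b <- g[r1 + dr, c1 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  cbind(a[ok], b[ok])
}

#' Gray-level co-occurrence matrix
#'
#' Counts of co-occurring level pairs at the given pixel offsets,
#' restricted to masked pairs, symmetrized (each pair counted in both
#' directions), summed over offsets and normalized to sum 1.
#'
#' @param d a \code{DiscretizedRegion} from [discretize()].
#' @param offsets list of length-2 integer offsets (row, col); default the
#'   four unique 2D directions (0,1), (1,1), (1,0), (1,-1).
#' @param normalize divide by the total count (default TRUE).
#' @return nLevels x nLevels matrix; attribute \code{degenerate} is TRUE
#'   when no valid pixel pair exists.
#' @export
glcmMatrix <- function(d, offsets = list(c(0, 1), c(1, 1), c(1, 0), c(1, -1)),
                       normalize = TRUE) {
  stopifnot(length(offsets) >= 1)
  ng <- d$nLevels
  P <- matrix(0, ng, ng)
  for (off in offsets) {
    if (all(off == 0)) stop("glcmMatrix: zero offset")
    pr <- shiftPairs(d, off[1], off[2])
    if (nrow(pr)) {
      t1 <- tabulate((pr[, 1] - 1L) * ng + pr[, 2], nbins = ng * ng)
      P <- P + matrix(t1, ng, ng, byrow = TRUE)
    }
  }
  P <- P + t(P)  # symmetrize
  tot <- sum(P)
  if (tot == 0) {
    attr(P, "degenerate") <- TRUE
    return(P)
  }
  if (normalize) P <- P / tot
  attr(P, "degenerate") <- FALSE
  P
}

#' Gray-level dependence matrix
#'
#' Element (g, j) counts masked pixels of level g having j - 1 dependent
#' 8-neighbours (a neighbour is dependent when its level differs from the
#' centre by at most \code{alpha}; neighbours outside the mask are
#' ignored).
#'
#' @param d a \code{DiscretizedRegion}.
#' @param alpha dependence tolerance on the level difference (default 0).
#' @return nLevels x (maxDependence + 1) count matrix with attribute
#'   \code{nPixels}.
#' @export
gldmMatrix <- function(d, alpha = 0L) {
  g <- d$gray
  dep <- matrix(0L, nrow(g), ncol(g))
  for (k in seq_len(nrow(NEIGH8))) {
    dr <- NEIGH8[k, 1]; dc <- NEIGH8[k, 2]
    nr <- nrow(g); nc <- ncol(g)
    if (max(1, 1 - dr) > min(nr, nr - dr) ||
        max(1, 1 - dc) > min(nc, nc - dc)) next
    r1 <- max(1, 1 - dr):min(nr, nr - dr)
    c1 <- max(1, 1 - dc):min(nc, nc - dc)
    a <- g[r1, c1, drop = FALSE]
    b <- g[r1 + dr, c1 + dc, drop = FALSE]
    hit <- !is.na(a) & !is.na(b) & abs(a - b) <= alpha
    inc <- matrix(0L, nr, nc)
    inc[r1, c1] <- hit
    dep <- dep + inc
  }
  centres <- which(!is.na(g))
  lev <- g[centres]; dp <- dep[centres] + 1L
  nd <- max(dp)
  M <- matrix(tabulate((lev - 1L) * nd + dp, nbins = d$nLevels * nd),
              d$nLevels, nd, byrow = TRUE)
  attr(M, "nPixels") <- length(centres)
  M
}

# 8-connected components of equal gray level within the mask, by iterative
# minimum-label propagation; returns an integer matrix of zone labels
zoneLabels8 <- function(gray) {
  nr <- nrow(gray); nc <- ncol(gray)
  lab <- matrix(seq_len(nr * nc), nr, nc)
  lab[is.na(gray)] <- NA_integer_
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(NEIGH8))) {
      dr <- NEIGH8[k, 1]; dc <- NEIGH8[k, 2]
      if (max(1, 1 - dr) > min(nr, nr - dr) ||
          max(1, 1 - dc) > min(nc, nc - dc)) next
      r1 <- max(1, 1 - dr):min(nr, nr - dr)
      c1 <- max(1, 1 - dc):min(nc, nc - dc)
      a <- lab[r1, c1, drop = FALSE]
      b <- lab[r1 + dr, c1 + dc, drop = FALSE]
      same <- !is.na(a) & !is.na(b) &
        gray[r1, c1, drop = FALSE] == gray[r1 + dr, c1 + dc, drop = FALSE]
      upd <- same & b < a
      if (any(upd)) {
        a[upd] <- b[upd]
        lab[r1, c1] <- a
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab
}

#' Gray-level size-zone matrix
#'
#' Zones are 8-connected components of equal gray level within the mask;
#' element (g, s) counts zones of level g and size s.
#'
#' @param d a \code{DiscretizedRegion}.
#' @return nLevels x maxZoneSize count matrix with attribute
#'   \code{nPixels}.
#' @export
glszmMatrix <- function(d) {
  lab <- zoneLabels8(d$gray)
  ids <- lab[!is.na(lab)]
  lev <- d$gray[!is.na(lab)]
  zoneSize <- tapply(ids, ids, length)
  zoneLevel <- tapply(lev, ids, function(x) x[1])
  ns <- max(zoneSize)
  M <- matrix(0, d$nLevels, ns)
  for (i in seq_along(zoneSize))
    M[zoneLevel[i], zoneSize[i]] <- M[zoneLevel[i], zoneSize[i]] + 1
  attr(M, "nPixels") <- length(ids)
  M
}

#' Gray-level run-length matrix
#'
#' Runs of identical level along each direction, broken by mask gaps;
#' element (g, l) counts runs of level g and length l, summed over the
#' directions.
#'
#' @param d a \code{DiscretizedRegion}.
#' @param directions list of length-2 integer direction vectors; default
#'   the four canonical 2D directions.
#' @return nLevels x maxRunLength count matrix with attributes
#'   \code{nPixels} and \code{nDirections}.
#' @export
glrlmMatrix <- function(d, directions = list(c(0, 1), c(1, 1), c(1, 0),
                                             c(1, -1))) {
  g <- d$gray
  nr <- nrow(g); nc <- ncol(g)
  g0 <- g; g0[is.na(g0)] <- 0L   # 0 breaks runs at mask gaps
  runs <- list()
  lineRuns <- function(vec) {
    r <- rle(vec)
    keep <- r$values > 0L
    if (!any(keep)) return(NULL)
    cbind(r$values[keep], r$lengths[keep])
  }
  collect <- function(lines) {
    for (v in lines) {
      rr <- lineRuns(v)
      if (!is.null(rr)) runs[[length(runs) + 1L]] <<- rr
    }
  }
  for (dir in directions) {
    dr <- dir[1]; dc <- dir[2]
    if (dr == 0 && dc == 1) {
      collect(split(as.vector(t(g0)), rep(seq_len(nr), each = nc)))  # rows
    } else if (dr == 1 && dc == 0) {
      collect(split(g0, rep(seq_len(nc), each = nr)))  # columns
    } else if (dr == 1 && dc == 1) {
      idx <- row(g0) - col(g0)
      collect(split(g0[order(idx, row(g0))], sort(idx)))
    } else if (dr == 1 && dc == -1) {
      idx <- row(g0) + col(g0)
      collect(split(g0[order(idx, row(g0))], sort(idx)))
    } else {
      stop("glrlmMatrix: unsupported direction (", dr, ",", dc, ")")
    }
  }
  allRuns <- do.call(rbind, runs)
  nl <- max(allRuns[, 2])
  M <- matrix(0, d$nLevels, nl)
  for (i in seq_len(nrow(allRuns)))
    M[allRuns[i, 1], allRuns[i, 2]] <- M[allRuns[i, 1], allRuns[i, 2]] + 1
  attr(M, "nPixels") <- sum(d$mask)
  attr(M, "nDirections") <- length(directions)
  M
}

#' Neighbouring gray-tone difference components
#'
#' For each level g: \code{s[g]} is the summed absolute difference between
#' pixels of level g and the mean of their masked 8-neighbours; \code{n[g]}
#' counts the contributing pixels (pixels with no masked neighbour are
#' excluded).
#'
#' @param d a \code{DiscretizedRegion}.
#' @return List with vectors \code{s}, \code{n} (length nLevels) and scalar
#'   \code{nValid}.
#' @export
ngtdmComponents <- function(d) {
  g <- d$gray
  nr <- nrow(g); nc <- ncol(g)
  gz <- g; gz[is.na(gz)] <- 0L
  msk <- !is.na(g)
  sumN <- matrix(0, nr, nc)
  cntN <- matrix(0L, nr, nc)
  for (k in seq_len(nrow(NEIGH8))) {
    dr <- NEIGH8[k, 1]; dc <- NEIGH8[k, 2]
    if (max(1, 1 - dr) > min(nr, nr - dr) ||
        max(1, 1 - dc) > min(nc, nc - dc)) next
    r1 <- max(1, 1 - dr):min(nr, nr - dr)
    c1 <- max(1, 1 - dc):min(nc, nc - dc)
    sumN[r1, c1] <- sumN[r1, c1] + gz[r1 + dr, c1 + dc]
    cntN[r1, c1] <- cntN[r1, c1] + msk[r1 + dr, c1 + dc]
  }
  valid <- msk & cntN > 0L
  ng <- d$nLevels
  s <- numeric(ng); n <- numeric(ng)
  if (any(valid)) {
    diffs <- abs(g[valid] - sumN[valid] / cntN[valid])
    lev <- g[valid]
    s <- as.numeric(tapply(diffs, factor(lev, levels = seq_len(ng)), sum))
    s[is.na(s)] <- 0
    n <- as.numeric(table(factor(lev, levels = seq_len(ng))))
  }
  list(s = s, n = n, nValid = sum(valid))
}
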