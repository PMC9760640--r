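#' Configuration for the intermediate image representations
#'
#' @param distancePower exponent applied to the per-cell normalized
#'   distances (default 3: cubing steepens the gradient so intensity
#'   peaks near the cell centre).
#' @param blurKernel Gaussian smoothing kernel size in voxels per axis
#'   (odd; default 5).
#' @param blurSigma Gaussian sigma in voxels (default 1, truncated to the
#'   \code{blurKernel} window).
#' @param closingRadius grayscale closing radius (voxels) used to fill
#'   small holes in the boundary representation.
#' @param inverseCap cap applied to the inverse distance-to-other-cells
#'   (default 1: a one-voxel gap saturates the proximity weight).
#' @return a validated list of class \code{reprConfig}.
#' @export
reprConfig <- function(distancePower = 3L, blurKernel = 5L, blurSigma = 1,
                       closingRadius = 1L, inverseCap = 1) {
  stopifnot(distancePower >= 1, blurKernel >= 1, blurKernel %% 2 == 1,
            blurSigma >= 0, closingRadius >= 0, inverseCap > 0)
  structure(list(distancePower = as.integer(distancePower),
                 blurKernel = as.integer(blurKernel), blurSigma = blurSigma,
                 closingRadius = as.integer(closingRadius),
                 inverseCap = inverseCap),
            class = "reprConfig")
}

# per-cell exact EDT: for every voxel of cell k, distance to the nearest
# voxel not belonging to cell k.  Computed per cell on its bounding box
# padded by one voxel (the pad ring is never part of the cell, so the
# nearest outside voxel is always inside the padded box).
# Returns list(raw = distances, rawSq = exact squared distances,
# norm = distances / per-cell max).
cellExteriorDistances <- function(labels) {
  d <- dim(labels)
  raw <- array(0, dim = d)
  rawSq <- array(0, dim = d)
  norm <- array(0, dim = d)
  coords <- splitCoords(labels)
  for (key in names(coords)) {
    co <- coords[[key]]
    k <- as.integer(key)
    lo <- pmax(apply(co, 2, min) - 1L, 1L)
    hi <- pmin(apply(co, 2, max) + 1L, d)
    sub <- labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    dist2 <- edtSquared(sub == k)
    inCell <- sub == k
    rawv <- sqrt(dist2[inCell])
    mx <- max(rawv)
    # map subvolume cell voxels back to full-volume coordinates
    subIdx <- which(inCell)
    subCo <- arrayInd(subIdx, dim(sub))
    fullIdx <- cbind(subCo[, 1] + lo[1] - 1L, subCo[, 2] + lo[2] - 1L,
                     subCo[, 3] + lo[3] - 1L)
    raw[fullIdx] <- rawv
    rawSq[fullIdx] <- dist2[inCell]
    norm[fullIdx] <- rawv / mx
  }
  list(raw = raw, rawSq = rawSq, norm = norm)
}

#' Raw per-cell distances to the nearest cell-exterior voxel
#'
#' For every voxel inside a cell, the exact Euclidean distance (voxel
#' units) to the nearest voxel that does not belong to that cell;
#' background is 0.  This is the quantity that, normalized per cell and
#' raised to \code{distancePower}, forms the distance representation.
#'
#' @param labels label volume.
#' @param squared return exact squared distances (integers) instead of
#'   distances; useful for exact comparisons.
#' @return numeric volume.
#' @export
rawExteriorDistances <- function(labels, squared = FALSE) {
  assertLabels(labels)
  res <- cellExteriorDistances(labels)
  if (squared) res$rawSq else res$raw
}

#' 'Distance to nearest cell exterior' representation
#'
#' Per cell: the Euclidean distance of each interior voxel to the nearest
#' voxel outside that cell, normalized to the cell's maximum, raised to
#' \code{distancePower}, then Gaussian-blurred.  Background voxels are 0
#' before blurring.
#'
#' @param labels label volume.
#' @param cfg a [reprConfig()].
#' @param blur apply the final Gaussian smoothing (set FALSE to inspect
#'   the pre-blur target).
#' @return numeric volume in [0, 1] (up to blur tolerance).
#' @export
distanceToExterior <- function(labels, cfg = reprConfig(), blur = TRUE) {
  assertLabels(labels)
  norm <- cellExteriorDistances(labels)$norm
  out <- norm^cfg$distancePower
  if (blur) out <- gaussianBlur(out, cfg$blurSigma, cfg$blurKernel)
  out
}

# distance from each voxel of each cell to the nearest voxel of a
# *different* cell, exact, via per-cell EDT on an adaptively grown
# window: a computed distance is trusted only if it is smaller than the
# window margin, otherwise the window is enlarged.
otherCellDistances <- function(labels) {
  d <- dim(labels)
  out <- array(0, dim = d)
  coords <- splitCoords(labels)
  ids <- as.integer(names(coords))
  if (length(ids) < 2L) {
    for (key in names(coords)) out[coords[[key]]] <- Inf
    return(out)
  }
  for (key in names(coords)) {
    co <- coords[[key]]
    k <- as.integer(key)
    W <- 10L
    repeat {
      lo <- pmax(apply(co, 2, min) - W, 1L)
      hi <- pmin(apply(co, 2, max) + W, d)
      full <- all(lo == 1L) && all(hi == d)
      sub <- labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
      other <- sub > 0 & sub != k
      if (!any(other)) {
        if (full) { out[co] <- Inf; break }
        W <- W * 2L
        next
      }
      dist2 <- edtSquared(!other)
      idx <- cbind(co[, 1] - lo[1] + 1L, co[, 2] - lo[2] + 1L,
                   co[, 3] - lo[3] + 1L)
      dv <- sqrt(dist2[idx])
      if (full || max(dv) <= W) { out[co] <- dv; break }
      W <- W * 2L
    }
  }
  out
}

#' 'Proximity enhanced cell boundary' representation
#'
#' Two ingredients are multiplied voxel-wise: (1) the binary cell map
#' minus the per-cell normalized exterior distances (high in the outer
#' shell of each cell, zero at its core), and (2) the inverse of the
#' Euclidean distance to the nearest voxel of a different cell, capped at
#' \code{inverseCap} (zero for an isolated cell).  Small holes are filled
#' by grayscale closing and the result is Gaussian-blurred.  The product
#' traces the full cell boundary while highlighting boundary segments
#' close to other cells.
#'
#' @param labels label volume.
#' @param cfg a [reprConfig()].
#' @param blur apply the final Gaussian smoothing.
#' @return numeric volume, zero on background before blurring.
#' @export
proximityBoundary <- function(labels, cfg = reprConfig(), blur = TRUE) {
  assertLabels(labels)
  norm <- cellExteriorDistances(labels)$norm
  A <- (labels > 0) - norm
  dOther <- otherCellDistances(labels)
  C <- ifelse(labels > 0, pmin(cfg$inverseCap, 1 / dOther), 0)
  out <- A * C
  if (cfg$closingRadius > 0) out <- grayClosing(out, cfg$closingRadius)
  if (blur) out <- gaussianBlur(out, cfg$blurSigma, cfg$blurKernel)
  out
}

#' Compute both intermediate representations from one label volume
#'
#' @param labels label volume.
#' @param cfg a [reprConfig()].
#' @return a [RepresentationPair].
#' @examples
#' lab <- array(0L, c(8, 8, 8)); lab[3:6, 3:6, 3:6] <- 1L
#' makeTrainingPair(lab)
#' @export
makeTrainingPair <- function(labels, cfg = reprConfig()) {
  assertLabels(labels)
  norm <- cellExteriorDistances(labels)$norm
  drep <- gaussianBlur(norm^cfg$distancePower, cfg$blurSigma, cfg$blurKernel)
  A <- (labels > 0) - norm
  dOther <- otherCellDistances(labels)
  C <- ifelse(labels > 0, pmin(cfg$inverseCap, 1 / dOther), 0)
  brep <- A * C
  if (cfg$closingRadius > 0) brep <- grayClosing(brep, cfg$closingRadius)
  brep <- gaussianBlur(brep, cfg$blurSigma, cfg$blurKernel)
  new("RepresentationPair", distRep = drep, boundaryRep = brep)
}
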