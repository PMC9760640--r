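#' Morphological shape features per segmented object
#'
#' For each labelled object: voxel volume, solidity (object volume
#' divided by the volume of its convex hull), and the three
#' ellipsoid-equivalent axis lengths derived from the principal moments
#' of the voxel cloud (length = 4 sqrt(eigenvalue), in voxels).  The
#' minor-axis ratio is reported in both orientations: \code{minorRatio}
#' = longer minor / shorter minor (>= 1) and \code{minorRatioInv} =
#' shorter / longer (<= 1, convenient for thresholding).
#'
#' The convex hull is built over the centres of the object's boundary
#' voxels (the usual region-properties convention), so a digitized
#' convex body scores a solidity close to 1.
#'
#' @param labels label volume with at least one object.
#' @return data.frame with one row per object: \code{id}, \code{volume},
#'   \code{solidity}, \code{majorAxis}, \code{minorAxisLong},
#'   \code{minorAxisShort}, \code{minorRatio}, \code{minorRatioInv}.
#' @examples
#' lab <- array(0L, c(12, 12, 24)); lab[4:9, 4:9, 4:21] <- 1L
#' shapeFeatures(lab)
#' @export
shapeFeatures <- function(labels) {
  assertLabels(labels)
  coords <- splitCoords(labels)
  if (length(coords) == 0L) stop("no objects in labels")
  bnd <- boundaryMask(labels)
  rows <- lapply(names(coords), function(key) {
    co <- coords[[key]]
    k <- as.integer(key)
    n <- nrow(co)
    # principal moments of the voxel point cloud (population covariance)
    ctr <- colMeans(co)
    cc <- sweep(co, 2, ctr)
    covm <- crossprod(cc) / n
    ev <- sort(eigen(covm, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    axes <- 4 * sqrt(pmax(ev, 1e-12))
    # hull over boundary-voxel centres
    bIdx <- which(bnd & labels == k)
    bco <- arrayInd(bIdx, dim(labels))
    if (nrow(bco) == 0) bco <- co
    hullVol <- cpp_hull_volume(matrix(as.numeric(bco), ncol = 3))
    data.frame(id = k, volume = n,
               solidity = if (hullVol > 0) min(1, n / hullVol) else 1,
               majorAxis = axes[1], minorAxisLong = axes[2],
               minorAxisShort = axes[3],
               minorRatio = axes[2] / max(axes[3], 1e-12),
               minorRatioInv = axes[3] / max(axes[2], 1e-12))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Project shape features onto the first two principal components
#'
#' Features are standardized (zero mean, unit variance per column) and
#' projected onto the first two principal components; constant columns
#' are dropped with a warning.
#'
#' @param features data.frame from [shapeFeatures()] (the \code{id}
#'   column, if present, is carried through but not projected).
#' @return list with \code{scores} (data.frame id/PC1/PC2) and
#'   \code{explained} (variance fractions of PC1 and PC2).
#' @export
pcaProject <- function(features) {
  ids <- if ("id" %in% names(features)) features$id else seq_len(nrow(features))
  num <- features[setdiff(names(features), "id")]
  num <- num[vapply(num, is.numeric, logical(1))]
  if (nrow(num) < 3L) stop("need at least 3 objects for PCA")
  keep <- vapply(num, function(col) stats::sd(col) > 0, logical(1))
  if (any(!keep)) {
    warning("dropping constant feature column(s): ",
            paste(names(num)[!keep], collapse = ", "))
    num <- num[keep]
  }
  pc <- stats::prcomp(num, center = TRUE, scale. = TRUE)
  scores <- data.frame(id = ids, PC1 = pc$x[, 1],
                       PC2 = if (ncol(pc$x) >= 2) pc$x[, 2] else 0)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores,
       explained = c(PC1 = expl[1], PC2 = if (length(expl) >= 2) expl[2] else 0))
}

#' Classify objects as physiologically reasonable rods or oddly shaped
#'
#' A transparent feature-threshold classifier: an object is a rod iff its
#' solidity and its shorter/longer minor-axis ratio are high (rod cross
#' sections are nearly circular and rods are convex) and, optionally, its
#' volume lies within plausible bounds for the configured cell
#' dimensions.  Merged, fragmented or noise-born objects fail one of the
#' criteria.
#'
#' @param features data.frame from [shapeFeatures()].
#' @param solidityMin minimum solidity for a rod.
#' @param minorRatioMin minimum shorter/longer minor-axis ratio.
#' @param volumeRange optional c(min, max) volume bounds in voxels, e.g.
#'   from [rodVolumeBounds()]; NULL disables the volume test.
#' @return character vector ("rod" or "odd"), one per row of
#'   \code{features}.
#' @export
classifyRod <- function(features, solidityMin = 0.85, minorRatioMin = 0.75,
                        volumeRange = NULL) {
  if (nrow(features) == 0L) return(character(0))
  ok <- features$solidity >= solidityMin &
        features$minorRatioInv >= minorRatioMin
  if (!is.null(volumeRange))
    ok <- ok & features$volume >= volumeRange[1] &
          features$volume <= volumeRange[2]
  ifelse(ok, "rod", "odd")
}

#' Plausible voxel-volume bounds for rod-shaped cells
#'
#' Bounds derived from the configured cell dimensions: from half a
#' newborn cell (half the division length) to 1.5 times a cell at the
#' division length.
#'
#' @param diameter cell diameter, micrometres.
#' @param divisionLength division length, micrometres.
#' @param voxelSize voxel size in micrometres (ZYX or scalar).
#' @return c(min, max) volume bounds in voxels.
#' @export
rodVolumeBounds <- function(diameter = 1, divisionLength = 3,
                            voxelSize = c(0.1, 0.1, 0.1)) {
  vv <- prod(rep(voxelSize, length.out = 3))
  c(0.5 * spherocylinderVolume(divisionLength / 2, diameter),
    1.5 * spherocylinderVolume(divisionLength, diameter)) / vv
}
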