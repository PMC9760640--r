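#' Simulate growth and division of a rod-shaped cell colony
#'
#' A minimal individual-based model of a growing biofilm: spherocylindrical
#' cells elongate at a constant per-cell rate (drawn once per cell with
#' +/- 10 percent jitter), divide into two end-to-end daughters once they
#' reach the division length, and are kept from overlapping by iterative
#' pairwise push-apart relaxation that enforces a minimum axis separation
#' of one cell diameter (minus a small overlap tolerance).  Cells sit on a
#' substrate at z = 0 and may not sink below it.
#'
#' The model stands in for a full biomechanical simulator: downstream
#' stages only consume its geometry (an overlap-free packing of rods with
#' lineage), not its mechanics.
#'
#' @param nSteps number of growth steps after the seed frame.
#' @param nSeedCells number of founder cells.
#' @param diameter cell diameter d in micrometres (default 1, E. coli-like;
#'   use 0.6 for S. oneidensis-like cells).
#' @param divisionLength tip-to-tip length l at which a cell divides, in
#'   micrometres (default 3; use 2 for S. oneidensis-like cells).
#' @param elongationRate mean elongation per step in micrometres.
#' @param birthLengthFrac daughter length as a fraction of the parent
#'   length at division.
#' @param divisionAngle angular perturbation applied to each daughter axis
#'   at division, in degrees.
#' @param overlapTol allowed overlap as a fraction of the diameter.
#' @param maxRelaxIter maximum push-apart sweeps per frame; exceeding it
#'   raises an error naming the frame.
#' @param seed integer RNG seed; the full frame list is reproducible.
#'
#' @return A list of colony frames.  Each frame is a data.frame with one
#'   row per cell and columns \code{id}, \code{parent} (NA for founders),
#'   \code{z}, \code{y}, \code{x} (centroid, micrometres), \code{az},
#'   \code{ay}, \code{ax} (unit orientation axis), \code{length},
#'   \code{diameter}, \code{growth}.  Frame t is element t + 1.
#'
#' @examples
#' frames <- growColony(nSteps = 10, nSeedCells = 1, seed = 1)
#' sapply(frames, nrow)
#' @seealso [voxelizeCells()], [colonyLineage()]
#' @export
growColony <- function(nSteps, nSeedCells = 1L, diameter = 1, divisionLength = 3,
                       elongationRate = 0.2, birthLengthFrac = 0.5,
                       divisionAngle = 5, overlapTol = 0.05,
                       maxRelaxIter = 500L, seed = 1L) {
  stopifnot(nSteps >= 0, nSeedCells >= 1, diameter > 0,
            divisionLength > diameter)
  withSeed(seed, {
    frames <- vector("list", nSteps + 1L)
    cells <- seedCells(nSeedCells, diameter, divisionLength, elongationRate)
    cells <- relaxFrame(cells, overlapTol, maxRelaxIter, frame = 0L)
    frames[[1L]] <- cells
    nextId <- max(cells$id) + 1L
    for (t in seq_len(nSteps)) {
      cells$length <- cells$length + cells$growth
      div <- which(cells$length >= divisionLength)
      if (length(div) > 0) {
        kept <- cells[-div, , drop = FALSE]
        daughters <- vector("list", length(div))
        for (k in seq_along(div)) {
          p <- cells[div[k], ]
          dl <- p$length * birthLengthFrac
          off <- p$length / 4
          ax <- c(p$az, p$ay, p$ax)
          ctr <- c(p$z, p$y, p$x)
          newAxes <- perturbAxis(rbind(ax, ax), divisionAngle * pi / 180)
          d1 <- ctr + off * ax
          d2 <- ctr - off * ax
          daughters[[k]] <- data.frame(
            id = c(nextId, nextId + 1L), parent = p$id,
            z = c(d1[1], d2[1]), y = c(d1[2], d2[2]), x = c(d1[3], d2[3]),
            az = newAxes[, 1], ay = newAxes[, 2], ax = newAxes[, 3],
            length = dl, diameter = p$diameter,
            growth = p$growth * stats::runif(2, 0.9, 1.1))
          nextId <- nextId + 2L
        }
        cells <- rbind(kept, do.call(rbind, daughters))
        cells <- cells[order(cells$id), , drop = FALSE]
        rownames(cells) <- NULL
      }
      cells <- relaxFrame(cells, overlapTol, maxRelaxIter, frame = t)
      frames[[t + 1L]] <- cells
    }
    frames
  })
}

seedCells <- function(n, diameter, divisionLength, elongationRate) {
  # founders start midway through the cycle, spread on the substrate
  spread <- max(divisionLength, diameter) * ceiling(sqrt(n))
  theta <- stats::runif(n, 0, 2 * pi)
  tilt <- stats::runif(n, -0.15, 0.15)
  az <- tilt
  ay <- sqrt(pmax(0, 1 - tilt^2)) * sin(theta)
  ax <- sqrt(pmax(0, 1 - tilt^2)) * cos(theta)
  len <- stats::runif(n, 0.55, 0.8) * divisionLength
  data.frame(
    id = seq_len(n), parent = NA_integer_,
    z = rep(diameter / 2, n),
    y = stats::runif(n, -spread / 2, spread / 2),
    x = stats::runif(n, -spread / 2, spread / 2),
    az = az, ay = ay, ax = ax,
    length = len, diameter = diameter,
    growth = elongationRate * stats::runif(n, 0.9, 1.1))
}

relaxFrame <- function(cells, overlapTol, maxIter, frame) {
  if (nrow(cells) < 2L) return(cells)
  res <- cpp_relax(as.matrix(cells[, c("z", "y", "x")]),
                   as.matrix(cells[, c("az", "ay", "ax")]),
                   cells$length, cells$diameter, overlapTol,
                   as.integer(maxIter), 1e-4)
  if (!res$converged)
    stop("overlap relaxation did not converge at frame ", frame)
  cells[, c("z", "y", "x")] <- res$centroid
  cells
}

#' Ground-truth lineage graph of a simulated colony
#'
#' Converts the frame list produced by [growColony()] into a
#' [LineageGraph]: one vertex per cell per frame (centroids in
#' micrometres, analytic spherocylinder volumes), a track edge wherever a
#' cell persists between consecutive frames, and parent-daughter edges
#' from a dividing cell to its two daughters.
#'
#' @param frames list of colony frames from [growColony()].
#' @return a [LineageGraph].
#' @export
colonyLineage <- function(frames) {
  verts <- do.call(rbind, lapply(seq_along(frames), function(t) {
    f <- frames[[t]]
    data.frame(frame = t, id = f$id, z = f$z, y = f$y, x = f$x,
               volume = spherocylinderVolume(f$length, f$diameter),
               length = f$length)
  }))
  edges <- list()
  for (t in seq_len(length(frames) - 1L)) {
    a <- frames[[t]]
    b <- frames[[t + 1L]]
    tracked <- intersect(a$id, b$id)
    if (length(tracked))
      edges[[length(edges) + 1L]] <- data.frame(
        fromFrame = t, fromId = tracked, toFrame = t + 1L, toId = tracked,
        type = "track")
    born <- b[!(b$id %in% a$id) & !is.na(b$parent), , drop = FALSE]
    born <- born[born$parent %in% a$id, , drop = FALSE]
    if (nrow(born))
      edges[[length(edges) + 1L]] <- data.frame(
        fromFrame = t, fromId = born$parent, toFrame = t + 1L, toId = born$id,
        type = "parent-daughter")
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(fromFrame = integer(), fromId = integer(),
               toFrame = integer(), toId = integer(), type = character())
  new("LineageGraph", vertices = verts, edges = edges)
}

#' Minimum pairwise surface separation in a frame
#'
#' Smallest gap between spherocylinder surfaces over all cell pairs
#' (negative values indicate residual overlap).  Used to verify the
#' minimum-distance criterion of the growth model.
#'
#' @param cells one colony frame (data.frame as returned by
#'   [growColony()]).
#' @return separation in micrometres (Inf for fewer than two cells).
#' @export
minSeparation <- function(cells) {
  if (nrow(cells) < 2L) return(Inf)
  cpp_min_separation(as.matrix(cells[, c("z", "y", "x")]),
                     as.matrix(cells[, c("az", "ay", "ax")]),
                     cells$length, cells$diameter)
}
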