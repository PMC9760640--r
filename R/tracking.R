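#' Tracking configuration
#'
#' @param maxLinkDistance maximum centroid distance for frame-to-frame
#'   linking, micrometres (1 for simulated data; 1.5 recommended for
#'   experimental data).
#' @param divisionMaxDistance maximum parent-daughter centroid distance,
#'   micrometres.
#' @param volumeRatio parent must be at least this many times larger
#'   than the daughter (default 1.5).
#' @param lengthRatio parent must be at least this many times longer
#'   than the daughter (default 1.5).
#' @return a validated list of class \code{trackingConfig}.
#' @export
trackingConfig <- function(maxLinkDistance = 1, divisionMaxDistance = maxLinkDistance,
                           volumeRatio = 1.5, lengthRatio = 1.5) {
  stopifnot(maxLinkDistance > 0, divisionMaxDistance > 0, volumeRatio > 0,
            lengthRatio > 0)
  structure(list(maxLinkDistance = maxLinkDistance,
                 divisionMaxDistance = divisionMaxDistance,
                 volumeRatio = volumeRatio, lengthRatio = lengthRatio),
            class = "trackingConfig")
}

#' Vertex table of one labelled frame
#'
#' Per-object centroid (micrometres), volume (cubic micrometres) and
#' ellipsoid-equivalent major axis length (micrometres) from a label
#' volume.
#'
#' @param labels label volume.
#' @param voxelSize voxel size in micrometres, ZYX.
#' @param frame frame index stored in the table.
#' @return data.frame with columns frame, id, z, y, x, volume, length.
#' @export
vertexTable <- function(labels, voxelSize = c(0.1, 0.1, 0.1), frame = 1L) {
  assertLabels(labels)
  coords <- splitCoords(labels)
  rows <- lapply(names(coords), function(key) {
    co <- sweep(coords[[key]], 2, c(0.5, 0.5, 0.5)) # voxel centres, 0-based
    co <- sweep(co, 2, voxelSize, "*")
    ctr <- colMeans(co)
    cc <- sweep(co, 2, ctr)
    covm <- crossprod(cc) / nrow(co)
    ev <- sort(eigen(covm, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    data.frame(frame = as.integer(frame), id = as.integer(key),
               z = ctr[1], y = ctr[2], x = ctr[3],
               volume = nrow(co) * prod(voxelSize),
               length = 4 * sqrt(max(ev[1], 0)))
  })
  if (length(rows) == 0L)
    return(data.frame(frame = integer(), id = integer(), z = numeric(),
                      y = numeric(), x = numeric(), volume = numeric(),
                      length = numeric()))
  out <- do.call(rbind, rows)
  out[order(out$id), , drop = FALSE]
}

#' Nearest-neighbour linking between two frames
#'
#' All candidate centroid pairs within \code{maxLinkDistance} are sorted
#' by distance (ties broken by smaller id in frame a, then frame b) and
#' accepted greedily, closest pairs first, each endpoint used at most
#' once.
#'
#' @param frameA,frameB vertex tables (see [vertexTable()]); centroids in
#'   micrometres.
#' @param cfg a [trackingConfig()].
#' @return data.frame with columns \code{fromId}, \code{toId},
#'   \code{distance}.
#' @export
linkFrames <- function(frameA, frameB, cfg = trackingConfig()) {
  if (nrow(frameA) == 0L || nrow(frameB) == 0L)
    return(data.frame(fromId = integer(), toId = integer(),
                      distance = numeric()))
  dz <- outer(frameA$z, frameB$z, "-")
  dy <- outer(frameA$y, frameB$y, "-")
  dx <- outer(frameA$x, frameB$x, "-")
  dd <- sqrt(dz^2 + dy^2 + dx^2)
  cand <- which(dd <= cfg$maxLinkDistance, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(data.frame(fromId = integer(), toId = integer(),
                      distance = numeric()))
  cand <- data.frame(a = cand[, 1], b = cand[, 2],
                     distance = dd[cand],
                     aId = frameA$id[cand[, 1]], bId = frameB$id[cand[, 2]])
  cand <- cand[order(cand$distance, cand$aId, cand$bId), , drop = FALSE]
  usedA <- logical(nrow(frameA))
  usedB <- logical(nrow(frameB))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!usedA[cand$a[i]] && !usedB[cand$b[i]]) {
      keep[i] <- TRUE
      usedA[cand$a[i]] <- TRUE
      usedB[cand$b[i]] <- TRUE
    }
  }
  out <- cand[keep, c("aId", "bId", "distance"), drop = FALSE]
  names(out) <- c("fromId", "toId", "distance")
  rownames(out) <- NULL
  out
}

#' Assign parents to unlinked cells (division detection)
#'
#' Every cell of frame b left unlinked by [linkFrames()] is assigned the
#' nearest frame-a cell within \code{divisionMaxDistance} whose volume
#' and length exceed the daughter's by the configured ratios and which
#' has fewer than two daughters already.  If the chosen parent also
#' carries a track link into frame b, that link is rewritten as the
#' second parent-daughter edge, so a division always yields two daughter
#' edges.
#'
#' @param frameA,frameB vertex tables.
#' @param links data.frame from [linkFrames()].
#' @param cfg a [trackingConfig()].
#' @return list with \code{track} (surviving track links) and
#'   \code{parentDaughter} (data.frame fromId/toId).
#' @export
detectDivisions <- function(frameA, frameB, links, cfg = trackingConfig()) {
  pd <- data.frame(fromId = integer(), toId = integer())
  unlinked <- setdiff(frameB$id, links$toId)
  # a parent's existing track link becomes a daughter edge on division,
  # so it counts towards the two-daughter cap
  nDaughters <- stats::setNames(rep(1L, nrow(links)),
                                as.character(links$fromId))
  for (bid in sort(unlinked)) {
    b <- frameB[frameB$id == bid, ]
    dzyx <- sqrt((frameA$z - b$z)^2 + (frameA$y - b$y)^2 + (frameA$x - b$x)^2)
    okDist <- dzyx <= cfg$divisionMaxDistance
    okVol <- frameA$volume >= cfg$volumeRatio * b$volume
    okLen <- frameA$length >= cfg$lengthRatio * b$length
    okCap <- vapply(frameA$id, function(id) {
      cur <- if (as.character(id) %in% names(nDaughters))
        nDaughters[[as.character(id)]] else 0L
      cur < 2L
    }, logical(1))
    cand <- which(okDist & okVol & okLen & okCap)
    if (length(cand) == 0L) next
    best <- cand[order(dzyx[cand], frameA$id[cand])][1]
    pid <- frameA$id[best]
    pd <- rbind(pd, data.frame(fromId = pid, toId = bid))
    key <- as.character(pid)
    nDaughters[key] <- (if (key %in% names(nDaughters)) nDaughters[[key]] else 0L) + 1L
  }
  # a dividing parent's track link becomes its second daughter edge
  if (nrow(pd) > 0) {
    reroute <- links$fromId %in% pd$fromId
    if (any(reroute)) {
      pd <- rbind(pd, data.frame(fromId = links$fromId[reroute],
                                 toId = links$toId[reroute]))
      links <- links[!reroute, , drop = FALSE]
    }
  }
  list(track = links, parentDaughter = pd)
}

#' Build a lineage graph across labelled frames
#'
#' Composes [linkFrames()] and [detectDivisions()] over consecutive
#' frames.  Every detected object becomes a vertex; unlinked objects
#' start new tracks.
#'
#' @param frames list of label volumes or of vertex tables.
#' @param cfg a [trackingConfig()].
#' @param voxelSize voxel size (micrometres, ZYX) used when frames are
#'   label volumes.
#' @return a [LineageGraph].
#' @examples
#' v1 <- data.frame(frame = 1L, id = 1L, z = 1, y = 1, x = 1,
#'                  volume = 2, length = 3)
#' v2 <- v1; v2$frame <- 2L; v2$x <- 1.2
#' buildLineage(list(v1, v2))
#' @export
buildLineage <- function(frames, cfg = trackingConfig(),
                         voxelSize = c(0.1, 0.1, 0.1)) {
  stopifnot(length(frames) >= 2L)
  tabs <- lapply(seq_along(frames), function(t) {
    f <- frames[[t]]
    if (is.array(f)) vertexTable(f, voxelSize, frame = t)
    else { f$frame <- as.integer(t); f }
  })
  verts <- do.call(rbind, tabs)
  edges <- list()
  for (t in seq_len(length(tabs) - 1L)) {
    a <- tabs[[t]]
    b <- tabs[[t + 1L]]
    if (nrow(a) == 0L || nrow(b) == 0L) next
    links <- linkFrames(a, b, cfg)
    div <- detectDivisions(a, b, links, cfg)
    if (nrow(div$track) > 0)
      edges[[length(edges) + 1L]] <- data.frame(
        fromFrame = t, fromId = div$track$fromId, toFrame = t + 1L,
        toId = div$track$toId, type = "track")
    if (nrow(div$parentDaughter) > 0)
      edges[[length(edges) + 1L]] <- data.frame(
        fromFrame = t, fromId = div$parentDaughter$fromId, toFrame = t + 1L,
        toId = div$parentDaughter$toId, type = "parent-daughter")
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(fromFrame = integer(), fromId = integer(),
               toFrame = integer(), toId = integer(), type = character())
  new("LineageGraph", vertices = verts, edges = edges)
}

#' Relative movement: the tracking difficulty measure
#'
#' For each cell j with a successor, RM is the ratio of (a) the distance
#' between cell j's centroids in frames i and i+1 to (b) the distance
#' from cell j's centroid in frame i to its closest neighbour in frame
#' i+1, excluding cell j's own successor.  Values near 0 indicate ample
#' temporal resolution; values near 1 mean nearest-neighbour tracking is
#' unreliable.
#'
#' @param graph a [LineageGraph] whose track edges define the
#'   frame-to-frame correspondence (ground truth or tracked).
#' @return list with \code{perFrame} (data.frame frame/meanRM/n),
#'   \code{rm} (data.frame of the individual ratios) and \code{mean}.
#' @export
relativeMovement <- function(graph) {
  stopifnot(is(graph, "LineageGraph"))
  v <- graph@vertices
  e <- graph@edges[graph@edges$type == "track", , drop = FALSE]
  if (nrow(e) == 0L) stop("graph has no track edges")
  out <- list()
  for (t in sort(unique(e$fromFrame))) {
    et <- e[e$fromFrame == t, , drop = FALSE]
    nxt <- v[v$frame == t + 1L, , drop = FALSE]
    if (nrow(nxt) < 2L) {
      warning("frame ", t, ": fewer than 2 cells in the next frame; RM skipped")
      next
    }
    for (i in seq_len(nrow(et))) {
      cur <- v[v$frame == t & v$id == et$fromId[i], ]
      succ <- nxt[nxt$id == et$toId[i], ]
      num <- sqrt((cur$z - succ$z)^2 + (cur$y - succ$y)^2 + (cur$x - succ$x)^2)
      others <- nxt[nxt$id != et$toId[i], , drop = FALSE]
      den <- min(sqrt((cur$z - others$z)^2 + (cur$y - others$y)^2 +
                      (cur$x - others$x)^2))
      if (den == 0) next
      out[[length(out) + 1L]] <- data.frame(frame = t, id = et$fromId[i],
                                            rm = num / den)
    }
  }
  if (length(out) == 0L) stop("RM undefined on every frame")
  rmTab <- do.call(rbind, out)
  perFrame <- aggregate(rm ~ frame, rmTab, mean)
  names(perFrame)[2] <- "meanRM"
  perFrame$n <- as.vector(table(rmTab$frame))
  list(perFrame = perFrame, rm = rmTab, mean = mean(rmTab$rm))
}

#' Downsample a lineage graph in time
#'
#' Keeps every \code{step}-th frame and renumbers frames consecutively.
#' Vertices at kept frames survive; an edge connects u (kept frame) to v
#' (next kept frame) iff v descends from u through the intervening
#' frames; its type is "track" if no division lies on the path and
#' "parent-daughter" otherwise.
#'
#' @param graph a [LineageGraph].
#' @param step keep every step-th frame (step = 1 returns the graph).
#' @return a [LineageGraph] on the kept frames.
#' @export
downsampleLineage <- function(graph, step) {
  stopifnot(is(graph, "LineageGraph"), step >= 1L)
  if (step == 1L) return(graph)
  v <- graph@vertices
  e <- graph@edges
  frames <- sort(unique(v$frame))
  kept <- frames[seq(1L, length(frames), by = step)]
  newIdx <- stats::setNames(seq_along(kept), kept)
  vOut <- v[v$frame %in% kept, , drop = FALSE]
  vOut$frame <- as.integer(newIdx[as.character(vOut$frame)])
  edges <- list()
  for (ki in seq_len(length(kept) - 1L)) {
    t0 <- kept[ki]
    t1 <- kept[ki + 1L]
    # descend from each vertex at t0 through t1 - t0 single-frame hops
    reach <- v[v$frame == t0, c("frame", "id"), drop = FALSE]
    reach$root <- reach$id
    reach$division <- FALSE
    for (t in t0:(t1 - 1L)) {
      et <- e[e$fromFrame == t, , drop = FALSE]
      hop <- merge(reach[reach$frame == t, ],
                   et, by.x = "id", by.y = "fromId")
      if (nrow(hop) == 0L) { reach <- reach[0, ]; break }
      reach <- data.frame(frame = hop$toFrame, id = hop$toId,
                          root = hop$root,
                          division = hop$division | hop$type == "parent-daughter")
    }
    if (nrow(reach) == 0L) next
    reach <- reach[order(reach$root, reach$id), , drop = FALSE]
    # guard: more than two descendants cannot be expressed as a division
    tab <- table(reach$root)
    over <- names(tab)[tab > 2]
    if (length(over)) {
      warning("downsampling produced >2 descendants for vertex id ",
              paste(over, collapse = ", "), "; keeping the first two")
      reach <- do.call(rbind, lapply(split(reach, reach$root), head, 2L))
    }
    tab <- table(reach$root)
    multi <- as.integer(names(tab)[tab > 1])
    edges[[length(edges) + 1L]] <- data.frame(
      fromFrame = ki, fromId = reach$root, toFrame = ki + 1L,
      toId = reach$id,
      type = ifelse(reach$division | reach$root %in% multi,
                    "parent-daughter", "track"))
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(fromFrame = integer(), fromId = integer(),
               toFrame = integer(), toId = integer(), type = character())
  rownames(edges) <- NULL
  new("LineageGraph", vertices = vOut, edges = edges)
}
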