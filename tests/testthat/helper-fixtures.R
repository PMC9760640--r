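# fixtures shared across the test files; everything is built in code

# single-slice volume holding a rasterized disk (diameter 20) inside an
# enclosing 20x20 square, embedded with a 2-voxel margin: the worked
# example used for the IoU and boundary-F1 metrics
diskSquareFixture <- function() {
  d <- c(1L, 24L, 24L)
  pred <- array(0L, d)
  ref <- array(0L, d)
  for (y in 1:20) for (x in 1:20) {
    ref[1, y + 2L, x + 2L] <- 1L
    if ((y - 10.5)^2 + (x - 10.5)^2 < 100) pred[1, y + 2L, x + 2L] <- 1L
  }
  list(pred = pred, ref = ref)
}

# axis-aligned solid ball as a label volume
ballVolume <- function(dim, centre, radius, label = 1L, base = NULL) {
  vol <- if (is.null(base)) array(0L, dim) else base
  g <- expand.grid(z = seq_len(dim[1]), y = seq_len(dim[2]),
                   x = seq_len(dim[3]))
  inside <- (g$z - centre[1])^2 + (g$y - centre[2])^2 +
            (g$x - centre[3])^2 <= radius^2
  vol[as.matrix(g)[inside, , drop = FALSE]] <- label
  vol
}

# cuboid block labelled volume
blockVolume <- function(dim, zr, yr, xr, label = 1L, base = NULL) {
  vol <- if (is.null(base)) array(0L, dim) else base
  vol[zr, yr, xr] <- label
  vol
}

# one spherocylinder cell row in the colony frame format
cellRow <- function(id, centre, axis, length, diameter, parent = NA_integer_) {
  axis <- axis / sqrt(sum(axis^2))
  data.frame(id = as.integer(id), parent = parent,
             z = centre[1], y = centre[2], x = centre[3],
             az = axis[1], ay = axis[2], ax = axis[3],
             length = length, diameter = diameter, growth = 0)
}

# random multi-blob label volume for EDT oracle tests
randomBlobVolume <- function(dim, nBlobs = 2L) {
  vol <- array(0L, dim)
  for (k in seq_len(nBlobs)) {
    ctr <- sapply(dim, function(n) sample(seq(3, max(3, n - 2)), 1))
    r <- sample(2:4, 1)
    vol <- ballVolume(dim, ctr, r, label = as.integer(k), base = vol)
  }
  vol
}

# brute-force per-cell distance to the nearest voxel not in the cell
# (squared, exact integers): the O(n^2) oracle
bruteExteriorDistSq <- function(labels) {
  d <- dim(labels)
  out <- array(0, d)
  for (k in unique(labels[labels > 0])) {
    inIdx <- which(labels == k)
    outIdx <- which(labels != k)
    coI <- arrayInd(inIdx, d)
    coO <- t(arrayInd(outIdx, d))
    for (i in seq_along(inIdx)) {
      out[inIdx[i]] <- min(colSums((coO - coI[i, ])^2))
    }
  }
  out
}

# tiny lineage graph from explicit tables
makeGraph <- function(vertices, edges = NULL) {
  if (is.null(edges))
    edges <- data.frame(fromFrame = integer(), fromId = integer(),
                        toFrame = integer(), toId = integer(),
                        type = character())
  new("LineageGraph", vertices = vertices, edges = edges)
}

# vertex table row
vRow <- function(frame, id, z = 0, y = 0, x = 0, volume = 1, length = 1) {
  data.frame(frame = as.integer(frame), id = as.integer(id),
             z = z, y = y, x = x, volume = volume, length = length)
}

# random small lineage graphs plus a perturbed estimate, for the AOGM
# oracle; returns list(gt, est)
randomGraphPair <- function(seed) {
  set.seed(seed)
  nFrames <- sample(2:3, 1)
  verts <- do.call(rbind, lapply(seq_len(nFrames), function(t) {
    n <- sample(2:4, 1)
    do.call(rbind, lapply(seq_len(n), function(i)
      vRow(t, i, z = runif(1), y = runif(1), x = runif(1))))
  }))
  edges <- list()
  for (t in seq_len(nFrames - 1L)) {
    a <- verts$id[verts$frame == t]
    b <- verts$id[verts$frame == t + 1L]
    nl <- min(length(a), length(b))
    use <- sample(seq_len(nl), sample(seq_len(nl), 1))
    for (i in use)
      edges[[length(edges) + 1L]] <- data.frame(
        fromFrame = t, fromId = a[i], toFrame = t + 1L, toId = b[i],
        type = sample(c("track", "parent-daughter"), 1, prob = c(.8, .2)))
  }
  gt <- makeGraph(verts, do.call(rbind, edges))
  # perturb: drop some vertices/edges, flip some semantics, add an edge
  ev <- lineageVertices(gt)
  ee <- lineageEdges(gt)
  if (nrow(ev) > 2 && runif(1) < 0.5)
    ev <- ev[-sample(nrow(ev), 1), , drop = FALSE]
  keepEdge <- paste(ee$fromFrame, ee$fromId) %in% paste(ev$frame, ev$id) &
              paste(ee$toFrame, ee$toId) %in% paste(ev$frame, ev$id)
  ee <- ee[keepEdge, , drop = FALSE]
  if (nrow(ee) > 0 && runif(1) < 0.5)
    ee <- ee[-sample(nrow(ee), 1), , drop = FALSE]
  if (nrow(ee) > 0 && runif(1) < 0.4) {
    i <- sample(nrow(ee), 1)
    ee$type[i] <- ifelse(ee$type[i] == "track", "parent-daughter", "track")
  }
  est <- tryCatch(makeGraph(ev, ee), error = function(e) NULL)
  if (is.null(est)) est <- makeGraph(ev)
  list(gt = gt, est = est)
}

# all permutations of a small id vector (rows of the returned matrix)
allPermutations <- function(ids) {
  if (length(ids) == 1L) return(matrix(ids, 1, 1))
  out <- NULL
  for (i in seq_along(ids)) {
    rest <- allPermutations(ids[-i])
    out <- rbind(out, cbind(ids[i], rest))
  }
  out
}

# independent AOGM oracle: recompute the six counts from scratch with
# adjacency tables under the identity correspondence
oracleAOGM <- function(est, gt) {
  gv <- lineageVertices(gt)
  evt <- lineageVertices(est)
  gk <- paste(gv$frame, gv$id)
  ek <- paste(evt$frame, evt$id)
  FN <- sum(!(gk %in% ek))
  FP <- sum(!(ek %in% gk))
  edgeKey <- function(e) paste(e$fromFrame, e$fromId, e$toFrame, e$toId)
  ge <- lineageEdges(gt)
  ee <- lineageEdges(est)
  # gt edges whose endpoints are both detected
  gDet <- (paste(ge$fromFrame, ge$fromId) %in% ek) &
          (paste(ge$toFrame, ge$toId) %in% ek)
  gkeys <- edgeKey(ge)
  ekeys <- edgeKey(ee)
  common <- intersect(gkeys[gDet], ekeys)
  EA <- nrow(ge) - length(common)
  ED <- nrow(ee) - length(common)
  gType <- setNames(ge$type, gkeys)
  eType <- setNames(ee$type, ekeys)
  EC <- sum(gType[common] != eType[common])
  c(NS = 0, FN = FN, FP = FP, ED = ED, EA = EA, EC = EC)
}
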