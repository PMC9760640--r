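#' AOGM operation weights
#'
#' Weights for the six graph operations: NS (split a merged detection),
#' FN (add a missing vertex), FP (delete a spurious vertex), ED (delete
#' an edge), EA (add an edge), EC (change an edge's semantics).
#'
#' @param preset \code{"edge"} = (0,0,0,1,1,1), scoring linking only;
#'   \code{"full"} = (1,1,1,1,1,1), scoring all six operations.
#' @param ns,fn,fp,ed,ea,ec individual non-negative weights, overriding
#'   the preset.
#' @return named numeric vector of length 6.
#' @export
aogmWeights <- function(preset = c("full", "edge"), ns = NULL, fn = NULL,
                        fp = NULL, ed = NULL, ea = NULL, ec = NULL) {
  preset <- match.arg(preset)
  w <- if (preset == "edge") c(NS = 0, FN = 0, FP = 0, ED = 1, EA = 1, EC = 1)
       else c(NS = 1, FN = 1, FP = 1, ED = 1, EA = 1, EC = 1)
  ov <- c(NS = ns, FN = fn, FP = fp, ED = ed, EA = ea, EC = ec)
  if (length(ov)) w[names(ov)] <- ov
  if (any(w < 0)) stop("weights must be non-negative")
  w
}

#' Match detections between estimated and reference label frames
#'
#' Detection test of the AOGM framework: a reference object is matched
#' to the estimated object that covers more than half of its voxels (at
#' most one such object exists).  Estimated objects claimed by two or
#' more reference objects yield missed splits (NS); unmatched reference
#' objects are false negatives; unclaimed estimated objects are false
#' positives.
#'
#' @param estFrames,gtFrames lists of label volumes, same length and
#'   shapes.
#' @return list with \code{correspondence} (data.frame frame/gtId/estId,
#'   estId NA when undetected) and counts \code{NS}, \code{FN},
#'   \code{FP}.
#' @export
matchVertices <- function(estFrames, gtFrames) {
  stopifnot(length(estFrames) == length(gtFrames))
  rows <- list()
  ns <- 0L
  fp <- 0L
  for (t in seq_along(gtFrames)) {
    est <- estFrames[[t]]
    gt <- gtFrames[[t]]
    if (!identical(dim(est), dim(gt))) stop("shape mismatch at frame ", t)
    ov <- overlapTable(est, gt)   # pred = est, ref = gt
    gtIds <- labelIds(gt)
    estId <- rep(NA_integer_, length(gtIds))
    if (nrow(ov$pairs) > 0) {
      cover <- ov$pairs$inter / ov$refSizes[ov$pairs$ref]
      good <- ov$pairs[cover > 0.5, , drop = FALSE]
      estId[match(good$ref, gtIds)] <- good$pred
    }
    claimed <- table(estId[!is.na(estId)])
    ns <- ns + sum(pmax(0L, as.integer(claimed) - 1L))
    fp <- fp + length(setdiff(labelIds(est), as.integer(names(claimed))))
    if (length(gtIds))
      rows[[length(rows) + 1L]] <- data.frame(frame = t, gtId = gtIds,
                                              estId = estId)
  }
  corr <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame = integer(), gtId = integer(), estId = integer())
  list(correspondence = corr, NS = ns,
       FN = sum(is.na(corr$estId)), FP = fp)
}

# identity correspondence: est vertex ids equal gt vertex ids per frame
identityCorrespondence <- function(gt, est) {
  v <- gt@vertices[, c("frame", "id"), drop = FALSE]
  names(v) <- c("frame", "gtId")
  ek <- paste(est@vertices$frame, est@vertices$id)
  v$estId <- ifelse(paste(v$frame, v$gtId) %in% ek, v$gtId, NA_integer_)
  v
}

#' AOGM score of an estimated lineage graph
#'
#' Counts the graph operations needed to turn the estimated graph into
#' the reference graph under a fixed vertex correspondence: FN/FP/NS
#' from the detection test, then ED (estimated edges with no reference
#' counterpart), EA (reference edges absent from the estimate) and EC
#' (edges present in both whose semantics differ).  The weighted sum is
#' normalized by AOGM0, the cost of building the reference graph from an
#' empty graph, giving TRA = 1 - min(AOGM, AOGM0) / AOGM0.
#'
#' @param est,gt [LineageGraph]s.
#' @param correspondence data.frame frame/gtId/estId (see
#'   [matchVertices()]); NULL matches vertices by identical (frame, id).
#' @param weights from [aogmWeights()].
#' @param detectionCounts optional list with NS/FN/FP from
#'   [matchVertices()]; when NULL they are derived from the
#'   correspondence (NS from duplicated est ids, FN from NA est ids, FP
#'   from est vertices never referenced).
#' @return an [AOGMReport].
#' @export
aogm <- function(est, gt, correspondence = NULL,
                 weights = aogmWeights("full"), detectionCounts = NULL) {
  stopifnot(is(est, "LineageGraph"), is(gt, "LineageGraph"))
  if (nrow(gt@vertices) == 0L) stop("AOGM0 undefined: empty reference graph")
  if (is.null(correspondence)) correspondence <- identityCorrespondence(gt, est)
  if (is.null(detectionCounts)) {
    key <- paste(correspondence$frame, correspondence$estId)
    dup <- table(key[!is.na(correspondence$estId)])
    detectionCounts <- list(
      NS = sum(pmax(0L, as.integer(dup) - 1L)),
      FN = sum(is.na(correspondence$estId)),
      FP = sum(!(paste(est@vertices$frame, est@vertices$id) %in% key)))
  }
  # map gt vertices to est vertices
  gk <- paste(correspondence$frame, correspondence$gtId)
  emap <- stats::setNames(correspondence$estId, gk)
  gtE <- gt@edges
  estE <- est@edges
  # reference edges translated into est-id space (NA if an endpoint is
  # undetected)
  gtFromEst <- emap[paste(gtE$fromFrame, gtE$fromId)]
  gtToEst <- emap[paste(gtE$toFrame, gtE$toId)]
  gtKey <- ifelse(is.na(gtFromEst) | is.na(gtToEst), NA,
                  paste(gtE$fromFrame, gtFromEst, gtE$toFrame, gtToEst))
  estKey <- paste(estE$fromFrame, estE$fromId, estE$toFrame, estE$toId)
  matched <- !is.na(gtKey) & gtKey %in% estKey
  EA <- sum(!matched)
  ED <- sum(!(estKey %in% gtKey[matched]))
  estType <- stats::setNames(estE$type, estKey)
  EC <- sum(matched & gtE$type != estType[gtKey])
  counts <- c(NS = detectionCounts$NS, FN = detectionCounts$FN,
              FP = detectionCounts$FP, ED = ED, EA = EA, EC = EC)
  a <- sum(weights * counts)
  a0 <- weights[["FN"]] * nrow(gt@vertices) + weights[["EA"]] * nrow(gtE)
  if (a0 <= 0) stop("AOGM0 undefined: zero-cost reference graph")
  new("AOGMReport", counts = counts, weights = weights, aogm = a, aogm0 = a0,
      tra = 1 - min(a, a0) / a0)
}

#' TRA_edge and TRA_full tracking accuracy
#'
#' Applies [aogm()] twice: with edge-only weights (0,0,0,1,1,1), scoring
#' the linking performance, and with equal weights on all six operations
#' (1,1,1,1,1,1).
#'
#' @inheritParams aogm
#' @return list with numeric \code{traEdge} and \code{traFull} plus the
#'   two [AOGMReport]s (\code{edgeReport}, \code{fullReport}).
#' @export
traScores <- function(est, gt, correspondence = NULL, detectionCounts = NULL) {
  re <- aogm(est, gt, correspondence, aogmWeights("edge"), detectionCounts)
  rf <- aogm(est, gt, correspondence, aogmWeights("full"), detectionCounts)
  list(traEdge = re@tra, traFull = rf@tra, edgeReport = re, fullReport = rf)
}
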