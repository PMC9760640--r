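#' Metrics configuration
#'
#' @param iouThreshold IoU matching threshold (default 0.5).
#' @param sbf1Tolerance distance error tolerance for the single-cell
#'   boundary F1 score, in voxels (default sqrt(3): one diagonal step).
#' @return a validated list of class \code{metricsConfig}.
#' @export
metricsConfig <- function(iouThreshold = 0.5, sbf1Tolerance = sqrt(3)) {
  stopifnot(iouThreshold > 0, iouThreshold <= 1, sbf1Tolerance >= 0)
  structure(list(iouThreshold = iouThreshold, sbf1Tolerance = sbf1Tolerance),
            class = "metricsConfig")
}

# overlap table between two label volumes: data.frame(pred, ref, inter)
# for all co-occurring nonzero pairs, plus per-object voxel counts
overlapTable <- function(pred, ref) {
  predSizes <- tabulate(pred[pred > 0], nbins = max(pred, 1L))
  refSizes <- tabulate(ref[ref > 0], nbins = max(ref, 1L))
  nz <- pred > 0 & ref > 0
  if (!any(nz)) {
    return(list(pairs = data.frame(pred = integer(), ref = integer(),
                                   inter = integer()),
                predSizes = predSizes, refSizes = refSizes))
  }
  p <- as.integer(pred[nz])
  r <- as.integer(ref[nz])
  enc <- (as.numeric(p) - 1) * (max(ref) + 1) + as.numeric(r)
  uenc <- sort(unique(enc))
  cnt <- tabulate(match(enc, uenc), nbins = length(uenc))
  list(pairs = data.frame(pred = as.integer((uenc - 1) %/% (max(ref) + 1)) + 1L,
                          ref = as.integer((uenc - 1) %% (max(ref) + 1)) + 1L,
                          inter = cnt),
       predSizes = predSizes, refSizes = refSizes)
}

#' Match predicted and reference objects by IoU
#'
#' All overlapping (predicted, reference) object pairs are scored by
#' Intersection-over-Union; pairs are then accepted greedily in
#' decreasing IoU order (ties broken by smaller predicted id, then
#' smaller reference id), each object used at most once, and pairs below
#' the threshold rejected.  Remaining objects are false positives
#' (predicted) and false negatives (reference).
#'
#' @param pred predicted label volume.
#' @param ref reference label volume of identical shape.
#' @param cfg a [metricsConfig()].
#' @return a [MatchResult].
#' @examples
#' a <- array(0L, c(4, 8, 8)); a[2:3, 2:4, 2:4] <- 1L; a[2:3, 6:8, 6:8] <- 2L
#' matchObjects(a, a)
#' @export
matchObjects <- function(pred, ref, cfg = metricsConfig()) {
  assertLabels(pred)
  assertLabels(ref)
  if (!identical(dim(pred), dim(ref))) stop("shape mismatch")
  ov <- overlapTable(pred, ref)
  pairs <- ov$pairs
  if (nrow(pairs) > 0) {
    pairs$iou <- pairs$inter /
      (ov$predSizes[pairs$pred] + ov$refSizes[pairs$ref] - pairs$inter)
    pairs <- pairs[order(-pairs$iou, pairs$pred, pairs$ref), , drop = FALSE]
    usedP <- logical(max(pred, 1L))
    usedR <- logical(max(ref, 1L))
    keep <- logical(nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      if (pairs$iou[i] < cfg$iouThreshold) break
      p <- pairs$pred[i]
      r <- pairs$ref[i]
      if (!usedP[p] && !usedR[r]) {
        keep[i] <- TRUE
        usedP[p] <- TRUE
        usedR[r] <- TRUE
      }
    }
    pairs <- pairs[keep, c("pred", "ref", "iou"), drop = FALSE]
    rownames(pairs) <- NULL
  } else {
    pairs <- data.frame(pred = integer(), ref = integer(), iou = numeric())
  }
  allP <- labelIds(pred)
  allR <- labelIds(ref)
  new("MatchResult", pairs = pairs,
      unmatchedPred = as.integer(setdiff(allP, pairs$pred)),
      unmatchedRef = as.integer(setdiff(allR, pairs$ref)),
      iouThreshold = cfg$iouThreshold)
}

#' Cell counting accuracy
#'
#' CA = TP / (TP + FP + FN) at the match's IoU threshold.
#'
#' @param m a [MatchResult].
#' @return fraction in [0, 1].
#' @export
countingAccuracy <- function(m) {
  stopifnot(is(m, "MatchResult"))
  tp <- nrow(m@pairs)
  fp <- length(m@unmatchedPred)
  fn <- length(m@unmatchedRef)
  if (tp + fp + fn == 0) stop("undefined CA: no objects in pred or ref")
  tp / (tp + fp + fn)
}

#' Single-cell segmentation accuracy
#'
#' Mean IoU over matched object pairs.
#'
#' @param m a [MatchResult] with at least one matched pair.
#' @return fraction in [iouThreshold, 1].
#' @export
ssa <- function(m) {
  stopifnot(is(m, "MatchResult"))
  if (nrow(m@pairs) == 0) stop("SSA undefined: no matched pairs")
  mean(m@pairs$iou)
}

#' Single-cell boundary F1 score
#'
#' For each matched pair, boundary voxels are object voxels with at least
#' one in-volume face neighbour outside the object.  Precision is the
#' fraction of predicted boundary voxels within \code{sbf1Tolerance}
#' (Euclidean) of any reference boundary voxel; recall is symmetric;
#' SBF1 is the mean per-pair F1 = 2PR/(P+R).
#'
#' @param pred predicted label volume.
#' @param ref reference label volume.
#' @param m a [MatchResult] for the two volumes.
#' @param cfg a [metricsConfig()].
#' @return fraction in [0, 1].
#' @export
sbf1 <- function(pred, ref, m, cfg = metricsConfig()) {
  stopifnot(is(m, "MatchResult"))
  if (nrow(m@pairs) == 0) stop("SBF1 undefined: no matched pairs")
  if (!identical(dim(pred), dim(ref))) stop("shape mismatch")
  bndP <- boundaryMask(pred)
  bndR <- boundaryMask(ref)
  tol2 <- cfg$sbf1Tolerance^2
  f1 <- numeric(nrow(m@pairs))
  for (i in seq_len(nrow(m@pairs))) {
    cp <- which(bndP & pred == m@pairs$pred[i])
    cr <- which(bndR & ref == m@pairs$ref[i])
    coP <- arrayInd(cp, dim(pred))
    coR <- arrayInd(cr, dim(ref))
    prec <- fracWithin(coP, coR, tol2, dim(pred))
    rec <- fracWithin(coR, coP, tol2, dim(pred))
    f1[i] <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }
  mean(f1)
}

# fraction of voxels in `from` within sqrt(tol2) of any voxel in `to`,
# via an exact EDT on the padded union bounding box
fracWithin <- function(from, to, tol2, fullDim) {
  if (nrow(from) == 0) return(0)
  if (nrow(to) == 0) return(0)
  pad <- ceiling(sqrt(tol2)) + 1L
  lo <- pmax(pmin(apply(from, 2, min), apply(to, 2, min)) - pad, 1L)
  hi <- pmin(pmax(apply(from, 2, max), apply(to, 2, max)) + pad, fullDim)
  d <- hi - lo + 1L
  mask <- array(1L, dim = d)
  mask[cbind(to[, 1] - lo[1] + 1L, to[, 2] - lo[2] + 1L,
             to[, 3] - lo[3] + 1L)] <- 0L
  dist2 <- edtSquared(mask)
  v <- dist2[cbind(from[, 1] - lo[1] + 1L, from[, 2] - lo[2] + 1L,
                   from[, 3] - lo[3] + 1L)]
  mean(v <= tol2 + 1e-9)
}

#' Full segmentation report over a grid of IoU thresholds
#'
#' Counting accuracy at each threshold of a grid, plus SSA and SBF1 at a
#' reference threshold.
#'
#' @param pred,ref label volumes.
#' @param thresholds IoU threshold grid.
#' @param cfg a [metricsConfig()]; its threshold is used for SSA/SBF1.
#' @return list with \code{caGrid} (data.frame threshold/CA), \code{ssa},
#'   \code{sbf1}, and the [MatchResult] at the reference threshold.
#' @export
segmentationReport <- function(pred, ref, thresholds = seq(0.05, 0.95, 0.05),
                               cfg = metricsConfig()) {
  ca <- vapply(thresholds, function(th) {
    countingAccuracy(matchObjects(pred, ref,
                                  metricsConfig(iouThreshold = th,
                                                sbf1Tolerance = cfg$sbf1Tolerance)))
  }, numeric(1))
  m <- matchObjects(pred, ref, cfg)
  list(caGrid = data.frame(threshold = thresholds, ca = ca),
       ssa = if (nrow(m@pairs) > 0) ssa(m) else NA_real_,
       sbf1 = if (nrow(m@pairs) > 0) sbf1(pred, ref, m, cfg) else NA_real_,
       match = m)
}
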