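#' RepresentationPair: the two intermediate image representations
#'
#' Holds the 'distance to nearest cell exterior' volume (\code{distRep})
#' and the 'proximity enhanced cell boundary' volume (\code{boundaryRep})
#' computed from one label volume.  Both are non-negative numeric arrays
#' with the shape of the source volume.
#'
#' @slot distRep numeric 3D array, per-cell normalized (and by default
#'   cubed, blurred) distance to the nearest voxel outside the cell.
#' @slot boundaryRep numeric 3D array, boundary representation weighted
#'   by proximity to other cells.
#'
#' @seealso [makeTrainingPair()], [distanceToExterior()],
#'   [proximityBoundary()]
#' @export
setClass("RepresentationPair",
  representation(distRep = "array", boundaryRep = "array"),
  validity = function(object) {
    d <- object@distRep
    b <- object@boundaryRep
    if (length(dim(d)) != 3L || length(dim(b)) != 3L)
      return("distRep and boundaryRep must be 3D arrays")
    if (!identical(dim(d), dim(b)))
      return("distRep and boundaryRep must have identical dimensions")
    if (anyNA(d) || anyNA(b) || any(!is.finite(d)) || any(!is.finite(b)))
      return("representations must be finite")
    if (min(d) < -1e-8 || min(b) < -1e-8)
      return("representations must be non-negative")
    TRUE
  }
)

#' MatchResult: object correspondence between two label volumes
#'
#' One-to-one IoU matching between predicted and reference objects, the
#' basis of the counting accuracy (CA), single-cell segmentation accuracy
#' (SSA) and single-cell boundary F1 (SBF1) metrics.
#'
#' @slot pairs data.frame with columns \code{pred}, \code{ref}, \code{iou};
#'   each predicted and each reference id appears at most once and every
#'   paired IoU is at least \code{iouThreshold}.
#' @slot unmatchedPred integer ids of unmatched predicted objects (false
#'   positives).
#' @slot unmatchedRef integer ids of unmatched reference objects (false
#'   negatives).
#' @slot iouThreshold the IoU matching threshold used.
#'
#' @seealso [matchObjects()], [countingAccuracy()], [ssa()], [sbf1()]
#' @export
setClass("MatchResult",
  representation(pairs = "data.frame", unmatchedPred = "integer",
                 unmatchedRef = "integer", iouThreshold = "numeric"),
  validity = function(object) {
    p <- object@pairs
    if (!all(c("pred", "ref", "iou") %in% names(p)))
      return("pairs needs columns pred, ref, iou")
    if (anyDuplicated(p$pred) || anyDuplicated(p$ref))
      return("each object may appear in at most one pair")
    if (nrow(p) > 0 && any(p$iou < object@iouThreshold - 1e-12))
      return("paired IoU below the matching threshold")
    if (length(object@iouThreshold) != 1L || object@iouThreshold <= 0 ||
        object@iouThreshold > 1)
      return("iouThreshold must be in (0, 1]")
    TRUE
  }
)

#' LineageGraph: cell detections over time with typed linkages
#'
#' Acyclic oriented graph in which vertices are cell detections (frame,
#' id, centroid in micrometres, volume, length) and edges connect
#' detections in consecutive frames, either as the same cell over time
#' (\code{"track"}) or as a division (\code{"parent-daughter"}).
#'
#' @slot vertices data.frame with columns \code{frame}, \code{id},
#'   \code{z}, \code{y}, \code{x}, \code{volume}, \code{length}.
#' @slot edges data.frame with columns \code{fromFrame}, \code{fromId},
#'   \code{toFrame}, \code{toId}, \code{type}.
#'
#' @seealso [buildLineage()], [colonyLineage()], [traScores()]
#' @export
setClass("LineageGraph",
  representation(vertices = "data.frame", edges = "data.frame"),
  validity = function(object) {
    v <- object@vertices
    e <- object@edges
    need_v <- c("frame", "id", "z", "y", "x", "volume", "length")
    need_e <- c("fromFrame", "fromId", "toFrame", "toId", "type")
    if (!all(need_v %in% names(v))) return("vertices lack required columns")
    if (!all(need_e %in% names(e))) return("edges lack required columns")
    if (anyDuplicated(v[c("frame", "id")]))
      return("duplicated (frame, id) vertex")
    if (nrow(e) > 0) {
      if (!all(e$type %in% c("track", "parent-daughter")))
        return("edge type must be 'track' or 'parent-daughter'")
      if (any(e$toFrame != e$fromFrame + 1L))
        return("edges must advance time by exactly one frame")
      vk <- paste(v$frame, v$id)
      if (!all(paste(e$fromFrame, e$fromId) %in% vk) ||
          !all(paste(e$toFrame, e$toId) %in% vk))
        return("edge endpoint not present in vertex table")
      if (anyDuplicated(e[c("toFrame", "toId")]))
        return("a vertex has more than one incoming edge")
      from <- paste(e$fromFrame, e$fromId)
      tr <- table(from[e$type == "track"])
      if (length(tr) && max(tr) > 1L)
        return("a vertex has more than one outgoing track edge")
      pd <- table(from[e$type == "parent-daughter"])
      if (length(pd) && max(pd) > 2L)
        return("a vertex has more than two daughters")
    }
    TRUE
  }
)

#' AOGMReport: graph-edit counts and the TRA score
#'
#' Result of comparing an estimated lineage graph with a reference graph
#' under the AOGM framework: the six operation counts (NS, FN, FP on
#' vertices; ED, EA, EC on edges), the weighted sums AOGM and AOGM0 (cost
#' of building the reference from an empty graph), and
#' TRA = 1 - min(AOGM, AOGM0)/AOGM0.
#'
#' @slot counts named numeric of length 6 (NS, FN, FP, ED, EA, EC).
#' @slot weights named numeric of length 6, the operation weights used.
#' @slot aogm weighted operation sum.
#' @slot aogm0 weighted cost of the reference graph from scratch.
#' @slot tra tracking accuracy in [0, 1].
#'
#' @seealso [aogm()], [traScores()]
#' @export
setClass("AOGMReport",
  representation(counts = "numeric", weights = "numeric", aogm = "numeric",
                 aogm0 = "numeric", tra = "numeric"),
  validity = function(object) {
    nm <- c("NS", "FN", "FP", "ED", "EA", "EC")
    if (!identical(names(object@counts), nm)) return("counts must be named NS..EC")
    if (!identical(names(object@weights), nm)) return("weights must be named NS..EC")
    if (any(object@counts < 0) || any(object@weights < 0))
      return("counts and weights must be non-negative")
    if (object@tra < -1e-12 || object@tra > 1 + 1e-12)
      return("tra must lie in [0, 1]")
    TRUE
  }
)

#' BiofilmPredictor: contract for image-to-representation predictors
#'
#' A predictor maps an intensity volume to a [RepresentationPair] of the
#' same shape.  The package ships [oraclePredictor()], which replays the
#' ground-truth representations and so exercises every downstream stage
#' without a trained network; a trained image-to-image model can be
#' plugged in by wrapping its forward pass in \code{predictFun}.
#'
#' @slot name character label for the predictor.
#' @slot predictFun function taking an intensity volume and returning a
#'   [RepresentationPair] with the same dimensions.
#'
#' @seealso [oraclePredictor()], [segmentImage()]
#' @export
setClass("BiofilmPredictor",
  representation(name = "character", predictFun = "function"))

#' @describeIn RepresentationPair-class dimensions of the representations
#' @param x a \code{RepresentationPair}
#' @export
setMethod("dim", "RepresentationPair", function(x) dim(x@distRep))

setMethod("show", "RepresentationPair", function(object) {
  cat("RepresentationPair\n")
  cat("  dim:", paste(dim(object@distRep), collapse = " x "), "(ZYX)\n")
  cat("  distRep range:", sprintf("[%.4g, %.4g]", min(object@distRep),
      max(object@distRep)), "\n")
  cat("  boundaryRep range:", sprintf("[%.4g, %.4g]", min(object@boundaryRep),
      max(object@boundaryRep)), "\n")
})

setMethod("show", "MatchResult", function(object) {
  cat("MatchResult (IoU threshold", object@iouThreshold, ")\n")
  cat("  TP:", nrow(object@pairs), " FP:", length(object@unmatchedPred),
      " FN:", length(object@unmatchedRef), "\n")
  if (nrow(object@pairs) > 0)
    cat("  mean matched IoU:", sprintf("%.4f", mean(object@pairs$iou)), "\n")
})

setMethod("show", "LineageGraph", function(object) {
  e <- object@edges
  cat("LineageGraph\n")
  cat("  frames:", length(unique(object@vertices$frame)),
      " vertices:", nrow(object@vertices), "\n")
  cat("  track edges:", sum(e$type == "track"),
      " parent-daughter edges:", sum(e$type == "parent-daughter"), "\n")
})

setMethod("show", "AOGMReport", function(object) {
  cat("AOGMReport\n")
  cat("  counts:", paste(names(object@counts), object@counts, sep = "=",
      collapse = " "), "\n")
  cat(sprintf("  AOGM: %g  AOGM0: %g  TRA: %.4f\n", object@aogm,
      object@aogm0, object@tra))
})

setMethod("show", "BiofilmPredictor", function(object) {
  cat("BiofilmPredictor:", object@name, "\n")
})

# ---- accessors -------------------------------------------------------------

#' Accessors for the core classes
#'
#' @param object a [RepresentationPair], [MatchResult], [LineageGraph] or
#'   [AOGMReport]
#' @return the corresponding component: a volume, a data.frame of matched
#'   pairs or graph vertices/edges, or a numeric score.
#' @name accessors
NULL

#' @rdname accessors
#' @export
distRep <- function(object) object@distRep

#' @rdname accessors
#' @export
boundaryRep <- function(object) object@boundaryRep

#' @rdname accessors
#' @export
matchedPairs <- function(object) object@pairs

#' @rdname accessors
#' @export
unmatchedPred <- function(object) object@unmatchedPred

#' @rdname accessors
#' @export
unmatchedRef <- function(object) object@unmatchedRef

#' @rdname accessors
#' @export
lineageVertices <- function(object) object@vertices

#' @rdname accessors
#' @export
lineageEdges <- function(object) object@edges

#' @rdname accessors
#' @export
traScore <- function(object) object@tra

#' @rdname accessors
#' @export
aogmCounts <- function(object) object@counts
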