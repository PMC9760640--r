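#' Single- and multilevel Otsu thresholds
#'
#' Histogram-based thresholding by maximizing between-class variance.
#' With \code{nClasses = 2} this is the classic single Otsu threshold;
#' larger values return \code{nClasses - 1} thresholds found by
#' exhaustive search over the binned histogram.
#'
#' @param values numeric vector to threshold.
#' @param nClasses number of intensity classes (2 to 4).
#' @param nBins number of histogram bins.
#' @return numeric vector of \code{nClasses - 1} thresholds (bin upper
#'   edges), increasing.
#' @export
otsuThresholds <- function(values, nClasses = 2L, nBins = 256L) {
  stopifnot(nClasses >= 2L, nClasses <= 4L, length(values) > 0)
  rng <- range(values)
  if (diff(rng) == 0) return(rep(rng[1], nClasses - 1L))
  br <- seq(rng[1], rng[2], length.out = nBins + 1L)
  h <- tabulate(pmin(nBins, pmax(1L, findInterval(values, br,
                rightmost.closed = TRUE))), nBins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-(nBins + 1L)]) / 2
  cw <- cumsum(p)
  cm <- cumsum(p * mids)
  # between-class contribution of bins (a, b]: w * mu^2
  term <- function(a, b) {
    w <- cw[b] - if (a > 0) cw[a] else 0
    m <- cm[b] - if (a > 0) cm[a] else 0
    ifelse(w > 0, m^2 / w, 0)
  }
  k <- nClasses - 1L
  best <- -Inf
  bestCut <- integer(k)
  if (k == 1L) {
    for (t1 in 1:(nBins - 1L)) {
      v <- term(0L, t1) + term(t1, nBins)
      if (v > best) { best <- v; bestCut <- t1 }
    }
  } else if (k == 2L) {
    for (t1 in 1:(nBins - 2L)) {
      a <- term(0L, t1)
      for (t2 in (t1 + 1L):(nBins - 1L)) {
        v <- a + term(t1, t2) + term(t2, nBins)
        if (v > best) { best <- v; bestCut <- c(t1, t2) }
      }
    }
  } else {
    step <- max(1L, nBins %/% 128L)
    cand <- seq(1L, nBins - 1L, by = step)
    for (t1 in cand) {
      a <- term(0L, t1)
      for (t2 in cand[cand > t1]) {
        ab <- a + term(t1, t2)
        for (t3 in cand[cand > t2]) {
          v <- ab + term(t2, t3) + term(t3, nBins)
          if (v > best) { best <- v; bestCut <- c(t1, t2, t3) }
        }
      }
    }
  }
  br[bestCut + 1L]
}

#' Post-processing configuration for representation-based segmentation
#'
#' @param otsuClasses classes for the multilevel Otsu used to pick seed
#'   voxels (default 3; seeds come from the top class).
#' @param minSeedVoxels connected seed components smaller than this are
#'   discarded.
#' @param minObjectVoxels final objects smaller than this are removed
#'   (default 30, about a tenth of an S. oneidensis cell at 0.1 µm
#'   voxels).
#' @param maskClosingRadius radius of the binary closing applied to the
#'   foreground mask.
#' @param maskRule how the foreground mask is thresholded from the
#'   distance representation D.  \code{"fixed"} (default) applies the
#'   absolute threshold \code{maskThreshold}: because D is a per-cell
#'   normalized distance raised to a power, its scale is [0, 1] by
#'   construction and a fixed low threshold cleanly separates the blur
#'   halo from cell voxels, recovering full cell extents.
#'   \code{"otsu"} uses the single Otsu threshold of D restricted to its
#'   nonzero support and \code{"multiotsu-low"} the lowest class
#'   boundary of a multilevel Otsu; both are histogram-driven and biased
#'   towards cell cores (the cubed distances concentrate most in-cell
#'   mass near 0), so they erode objects and are provided for
#'   comparison.
#' @param maskThreshold absolute foreground threshold on D used by
#'   \code{maskRule = "fixed"}.
#' @return a validated list of class \code{postProcessConfig}.
#' @export
postProcessConfig <- function(otsuClasses = 3L, minSeedVoxels = 5L,
                              minObjectVoxels = 30L, maskClosingRadius = 1L,
                              maskRule = c("fixed", "otsu", "multiotsu-low"),
                              maskThreshold = 0.007) {
  maskRule <- match.arg(maskRule)
  stopifnot(otsuClasses >= 2L, minSeedVoxels >= 0L, minObjectVoxels >= 0L,
            maskClosingRadius >= 0L, maskThreshold > 0)
  structure(list(otsuClasses = as.integer(otsuClasses),
                 minSeedVoxels = as.integer(minSeedVoxels),
                 minObjectVoxels = as.integer(minObjectVoxels),
                 maskClosingRadius = as.integer(maskClosingRadius),
                 maskRule = maskRule, maskThreshold = maskThreshold),
            class = "postProcessConfig")
}

#' Instance segmentation from a pair of intermediate representations
#'
#' Deterministic post-processing of the distance (D) and boundary (B)
#' representations: (1) a foreground mask is thresholded from D (see
#' \code{maskRule}) and morphologically closed; (2) seed markers are the
#' 6-connected components of the voxels whose D - B value falls in the
#' top class of a multilevel Otsu (computed over the mask support),
#' components below \code{minSeedVoxels} discarded; (3) a seeded
#' watershed on the elevation B - D, restricted to the mask, grows one
#' region per seed; (4) objects below \code{minObjectVoxels} are removed
#' and labels are compacted.
#'
#' @param pair a [RepresentationPair] (negative values are clipped to 0).
#' @param cfg a [postProcessConfig()].
#' @return integer label volume; every foreground voxel carries exactly
#'   one label and the label count equals the surviving seed count.
#' @export
segmentRepresentation <- function(pair, cfg = postProcessConfig()) {
  stopifnot(is(pair, "RepresentationPair"))
  D <- pmax(pair@distRep, 0)
  B <- pmax(pair@boundaryRep, 0)
  d <- dim(D)
  support <- D > 0
  if (!any(support)) return(array(0L, dim = d))

  thr <- switch(cfg$maskRule,
    "fixed" = cfg$maskThreshold,
    "otsu" = otsuThresholds(D[support], 2L),
    "multiotsu-low" = otsuThresholds(D[support], cfg$otsuClasses)[1L])
  mask <- D >= thr
  if (cfg$maskClosingRadius > 0) {
    m <- grayClosing(array(as.numeric(mask), dim = d), cfg$maskClosingRadius)
    mask <- m > 0.5
  }
  if (!any(mask)) return(array(0L, dim = d))

  S <- D - B
  st <- otsuThresholds(S[mask], cfg$otsuClasses)
  seedMask <- mask & (S >= st[length(st)])
  seeds <- labelComponents6(seedMask)
  if (cfg$minSeedVoxels > 0 && max(seeds) > 0) {
    sizes <- tabulate(seeds[seeds > 0], nbins = max(seeds))
    drop <- which(sizes < cfg$minSeedVoxels)
    if (length(drop)) seeds[seeds %in% drop] <- 0L
  }
  if (max(seeds) == 0) return(array(0L, dim = d))

  lab <- array(cpp_watershed(as.numeric(B - D), as.integer(seeds),
                             as.integer(mask), as.integer(d)), dim = d)
  if (cfg$minObjectVoxels > 0 && max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    drop <- which(sizes < cfg$minObjectVoxels)
    if (length(drop)) lab[lab %in% drop] <- 0L
  }
  compactLabels(lab)
}

# relabel 1..n preserving the order of first appearance by original id
compactLabels <- function(lab) {
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) == 0L) {
    storage.mode(lab) <- "integer"
    return(lab)
  }
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  out <- lab
  out[lab > 0] <- map[lab[lab > 0]]
  storage.mode(out) <- "integer"
  out
}

#' Oracle predictor: ground-truth representations as a predictor
#'
#' Returns a [BiofilmPredictor] that ignores its intensity input and
#' emits the intermediate representations computed from the given label
#' volume.  This desk-scale stand-in for a trained image-to-image network
#' makes every downstream stage (thresholding, watershed, metrics,
#' tracking) testable against known ground truth.
#'
#' @param labels label volume.
#' @param cfg a [reprConfig()].
#' @return a [BiofilmPredictor].
#' @export
oraclePredictor <- function(labels, cfg = reprConfig()) {
  assertLabels(labels)
  pair <- makeTrainingPair(labels, cfg)
  expected <- dim(labels)
  new("BiofilmPredictor", name = "oracle",
      predictFun = function(image) {
        if (!identical(dim(image), expected))
          stop("image shape does not match the oracle's label volume")
        pair
      })
}

#' Wrap a prediction function as a predictor
#'
#' @param name label for the predictor.
#' @param predictFun function mapping an intensity volume to a
#'   [RepresentationPair] of the same shape.
#' @return a [BiofilmPredictor].
#' @export
asPredictor <- function(name, predictFun) {
  new("BiofilmPredictor", name = name, predictFun = predictFun)
}

#' End-to-end segmentation of an intensity volume
#'
#' Runs the predictor to obtain the intermediate representations, then
#' [segmentRepresentation()].  Deterministic given a deterministic
#' predictor.
#'
#' @param image intensity volume.
#' @param predictor a [BiofilmPredictor].
#' @param cfg a [postProcessConfig()].
#' @return integer label volume.
#' @export
segmentImage <- function(image, predictor, cfg = postProcessConfig()) {
  assertVolume(image)
  stopifnot(is(predictor, "BiofilmPredictor"))
  pair <- predictor@predictFun(image)
  if (!is(pair, "RepresentationPair"))
    stop("predictor did not return a RepresentationPair")
  if (!identical(dim(pair), dim(image)))
    stop("predictor output shape does not match the input image")
  segmentRepresentation(pair, cfg)
}
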