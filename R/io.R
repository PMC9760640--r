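#' Read a volume from a multi-page TIFF
#'
#' Pages are Z planes (ZYX order).  Label volumes are read as integers;
#' intensity volumes as numerics; stored values pass through unchanged.
#'
#' @param path TIFF file path.
#' @param type \code{"labels"} forces integer storage, \code{"intensity"}
#'   numeric, \code{"auto"} decides from the sample format.
#' @return 3D array, dim c(nz, ny, nx).
#' @export
readVolume <- function(path, type = c("auto", "labels", "intensity")) {
  type <- match.arg(type)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1L) stop("ragged TIFF pages")
  d <- c(length(pages), dims[[1]])
  vol <- array(0, dim = d)
  for (z in seq_along(pages)) vol[z, , ] <- pages[[z]]
  isInt <- all(vol == round(vol))
  if (type == "labels" || (type == "auto" && isInt)) {
    if (max(vol) > .Machine$integer.max) stop("label overflow")
    storage.mode(vol) <- "integer"
  }
  vol
}

#' Write a volume as a multi-page TIFF
#'
#' Labels are stored as 16-bit unsigned integers; ids beyond the 16-bit
#' cap (65,534) raise an error.  Intensities are stored as 16-bit
#' unsigned photon counts (values are rounded; fractional photons are
#' far below the shot noise).
#'
#' @param vol 3D array.
#' @param path output path.
#' @param type \code{"labels"} or \code{"intensity"}.
#' @return the path, invisibly.
#' @export
writeVolume <- function(vol, path, type = c("labels", "intensity")) {
  assertVolume(vol)
  type <- match.arg(type)
  d <- dim(vol)
  v <- round(vol)
  if (type == "labels" && max(v) > 65534)
    stop("label overflow: more than 65534 labels exceed 16-bit storage")
  if (max(v) > 65535)
    stop("intensity overflow: values exceed 16-bit storage")
  if (min(v) < 0) stop("negative values cannot be stored")
  pages <- lapply(seq_len(d[1]), function(z)
    matrix(as.numeric(v[z, , ]) / 65535, d[2], d[3]))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write / read a lineage graph as CSV tables
#'
#' \code{writeLineage} stores \code{vertices.csv} and \code{edges.csv}
#' in a directory plus \code{tracks.txt}, a cell-tracking-challenge
#' style track summary (track id, start frame, end frame, parent track
#' id), where a track is a maximal chain of track edges.
#'
#' @param graph a [LineageGraph].
#' @param dir output directory (created if missing).
#' @return \code{writeLineage}: the directory, invisibly;
#'   \code{readLineage}: a [LineageGraph].
#' @export
writeLineage <- function(graph, dir) {
  stopifnot(is(graph, "LineageGraph"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(graph@vertices, file.path(dir, "vertices.csv"), row.names = FALSE)
  write.csv(graph@edges, file.path(dir, "edges.csv"), row.names = FALSE)
  tr <- trackTable(graph)
  write.table(tr, file.path(dir, "tracks.txt"), row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname writeLineage
#' @export
readLineage <- function(dir) {
  v <- read.csv(file.path(dir, "vertices.csv"))
  e <- read.csv(file.path(dir, "edges.csv"))
  if (nrow(e) == 0L)
    e <- data.frame(fromFrame = integer(), fromId = integer(),
                    toFrame = integer(), toId = integer(), type = character())
  new("LineageGraph", vertices = v, edges = e)
}

# decompose a lineage graph into tracks: maximal chains of track edges.
# Returns data.frame(track, start, end, parentTrack); parent 0 = none.
trackTable <- function(graph) {
  v <- graph@vertices
  e <- graph@edges
  key <- function(f, i) paste(f, i, sep = ":")
  vk <- key(v$frame, v$id)
  succ <- stats::setNames(rep(NA_character_, length(vk)), vk)
  tr <- e[e$type == "track", , drop = FALSE]
  succ[key(tr$fromFrame, tr$fromId)] <- key(tr$toFrame, tr$toId)
  hasIncomingTrack <- vk %in% succ[!is.na(succ)]
  trackOf <- stats::setNames(integer(length(vk)), vk)
  starts <- vk[!hasIncomingTrack]
  tracks <- list()
  for (s in starts) {
    id <- length(tracks) + 1L
    cur <- s
    first <- v$frame[vk == s]
    last <- first
    while (TRUE) {
      trackOf[cur] <- id
      last <- v$frame[vk == cur]
      nxt <- succ[[cur]]
      if (is.na(nxt)) break
      cur <- nxt
    }
    tracks[[id]] <- data.frame(track = id, start = first, end = last,
                               startKey = s)
  }
  tab <- do.call(rbind, tracks)
  pd <- e[e$type == "parent-daughter", , drop = FALSE]
  parentOf <- stats::setNames(trackOf[key(pd$fromFrame, pd$fromId)],
                              key(pd$toFrame, pd$toId))
  tab$parent <- ifelse(tab$startKey %in% names(parentOf),
                       parentOf[tab$startKey], 0L)
  tab[c("track", "start", "end", "parent")]
}

#' Write the simulated colony lineage as CSV
#'
#' One row per cell per frame: id, parent id, frame, centroid (z, y, x,
#' micrometres), length and diameter.
#'
#' @param frames list of colony frames from [growColony()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeColonyCSV <- function(frames, path) {
  rows <- do.call(rbind, lapply(seq_along(frames), function(t) {
    f <- frames[[t]]
    data.frame(id = f$id, parent_id = f$parent, frame = t - 1L,
               z = f$z, y = f$y, x = f$x, length = f$length,
               diameter = f$diameter)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
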