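# internal helpers shared across modules

# evaluate expr under a fixed RNG seed, restoring global RNG state after
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

assertVolume <- function(x, name = deparse(substitute(x))) {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop(name, " must be a 3D array (ZYX order)", call. = FALSE)
  invisible(x)
}

assertLabels <- function(x, name = deparse(substitute(x))) {
  assertVolume(x, name)
  if (anyNA(x) || any(x < 0))
    stop(name, " must be a non-negative integer label volume", call. = FALSE)
  invisible(x)
}

# integer storage for C++ kernels
asIntVolume <- function(x) {
  storage.mode(x) <- "integer"
  x
}

labelIds <- function(labels) {
  ids <- sort(unique(as.vector(labels)))
  ids[ids > 0L]
}

# squared EDT to nearest zero voxel of `mask` (1 = object); exact integers
edtSquared <- function(mask) {
  d <- dim(mask)
  array(cpp_edt_sq(as.integer(mask != 0), as.integer(d)), dim = d)
}

gaussianBlur <- function(vol, sigma = 1, ksize = 5) {
  d <- dim(vol)
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  array(cpp_gaussian_blur(as.numeric(vol), as.integer(d), as.numeric(sigma),
                          as.integer(ksize)), dim = d)
}

grayClosing <- function(vol, radius = 1) {
  d <- dim(vol)
  dil <- cpp_box_filter(as.numeric(vol), as.integer(d), as.integer(radius), TRUE)
  array(cpp_box_filter(dil, as.integer(d), as.integer(radius), FALSE), dim = d)
}

labelComponents6 <- function(mask) {
  d <- dim(mask)
  array(cpp_label6(as.integer(mask != 0), as.integer(d)), dim = d)
}

boundaryMask <- function(labels) {
  d <- dim(labels)
  array(cpp_boundary6(as.integer(labels), as.integer(d)), dim = d)
}

# voxel coordinates (1-based array indices) of every foreground voxel,
# split by label id
splitCoords <- function(labels) {
  idx <- which(labels > 0)
  if (length(idx) == 0L) return(list())
  co <- arrayInd(idx, dim(labels))
  lab <- labels[idx]
  lapply(split(seq_along(idx), lab), function(i) co[i, , drop = FALSE])
}

# analytic spherocylinder volume (cylinder of length l - d plus sphere)
spherocylinderVolume <- function(length, diameter) {
  r <- diameter / 2
  pi * r^2 * pmax(0, length - diameter) + 4 / 3 * pi * r^3
}

# rotate unit vectors by `angle` radians about a random perpendicular axis
perturbAxis <- function(axes, angle) {
  out <- axes
  for (i in seq_len(nrow(axes))) {
    a <- axes[i, ]
    # random direction perpendicular to a
    repeat {
      v <- stats::rnorm(3)
      v <- v - sum(v * a) * a
      nv <- sqrt(sum(v^2))
      if (nv > 1e-8) break
    }
    v <- v / nv
    b <- cos(angle) * a + sin(angle) * v
    out[i, ] <- b / sqrt(sum(b^2))
  }
  out
}
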