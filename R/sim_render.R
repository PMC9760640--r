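#' Rendering configuration for simulated biofilm images
#'
#' Collects the optical and noise parameters of the virtual microscope.
#' The detection model is: emitters (fluorophores) are placed at random in
#' the cell interior (cytosolic labelling) or on the cell surface
#' (membrane staining), binned into voxels, convolved with the point
#' spread function, a constant background is added, and the expected
#' image is corrupted by Poisson shot noise plus Gaussian read noise.
#'
#' @param voxelSize voxel edge lengths in micrometres, ZYX.
#' @param psf optional measured PSF volume (3D array); must sum to 1.
#'   When NULL, an anisotropic Gaussian PSF is used.
#' @param psfSigma Gaussian PSF sigmas in micrometres, ZYX (light-sheet
#'   PSFs are elongated along z; default z sigma is 2.5x the lateral one).
#' @param labelingMode \code{"cytosolic"} or \code{"membrane"}.
#' @param fluorophoresPerCell mean number of emitters per cell.
#' @param photonsPerFluorophore mean detected photons per emitter; ignored
#'   when \code{targetSBR} is given.
#' @param targetSBR if non-NULL, the emitter brightness is solved so the
#'   noiseless image reaches this signal-to-background ratio (mean
#'   intensity over cell voxels divided by mean over near-cell background).
#' @param backgroundMean constant background, photons per voxel.
#' @param readNoise Gaussian read noise RMS in photons per voxel
#'   (detector-calibrated default 3.04).
#'
#' @return a validated list of class \code{renderConfig}.
#' @export
renderConfig <- function(voxelSize = c(0.1, 0.1, 0.1), psf = NULL,
                         psfSigma = c(0.25, 0.1, 0.1),
                         labelingMode = c("cytosolic", "membrane"),
                         fluorophoresPerCell = 500,
                         photonsPerFluorophore = 10,
                         targetSBR = NULL, backgroundMean = 100,
                         readNoise = 3.04) {
  labelingMode <- match.arg(labelingMode)
  stopifnot(length(voxelSize) == 3L, all(voxelSize > 0), readNoise >= 0,
            backgroundMean >= 0, fluorophoresPerCell >= 0)
  if (!is.null(psf)) {
    assertVolume(psf, "psf")
    if (any(psf < 0)) stop("psf must be non-negative")
    if (abs(sum(psf) - 1) > 1e-6) stop("psf must be normalized to sum 1")
  }
  if (!is.null(targetSBR) && targetSBR <= 1)
    stop("targetSBR must exceed 1")
  structure(list(voxelSize = voxelSize, psf = psf, psfSigma = psfSigma,
                 labelingMode = labelingMode,
                 fluorophoresPerCell = fluorophoresPerCell,
                 photonsPerFluorophore = photonsPerFluorophore,
                 targetSBR = targetSBR, backgroundMean = backgroundMean,
                 readNoise = readNoise),
            class = "renderConfig")
}

#' Volume geometry that fits a set of cells
#'
#' Computes an origin (micrometres) and array dimensions so that all
#' cells, plus a margin, fit in the voxel grid.
#'
#' @param cells colony frame data.frame.
#' @param voxelSize voxel size in micrometres, ZYX.
#' @param margin clearance around the cells in micrometres.
#' @return list with \code{origin} (µm, ZYX) and \code{dim} (voxels, ZYX).
#' @export
colonyGeometry <- function(cells, voxelSize = c(0.1, 0.1, 0.1), margin = 1) {
  h <- (cells$length - cells$diameter) / 2 + cells$diameter / 2
  lo <- c(min(cells$z - h), min(cells$y - h), min(cells$x - h)) - margin
  hi <- c(max(cells$z + h), max(cells$y + h), max(cells$x + h)) + margin
  lo[1] <- min(lo[1], 0)  # keep the substrate in view
  list(origin = lo, dim = as.integer(ceiling((hi - lo) / voxelSize)))
}

#' Voxelize spherocylindrical cells into a label volume
#'
#' A voxel is assigned label k iff its centre lies inside cell k's
#' spherocylinder; where relaxed cells still overlap within tolerance,
#' the voxel goes to the cell with the smaller axis distance, then the
#' smaller id.  Cells extending beyond the volume are clipped with a
#' warning.
#'
#' @param cells colony frame data.frame (see [growColony()]).
#' @param dim volume dimensions c(nz, ny, nx).
#' @param voxelSize voxel size in micrometres, ZYX.
#' @param origin physical position of the volume corner in micrometres.
#' @return integer label volume.
#' @examples
#' cell <- data.frame(id = 1L, parent = NA, z = 1, y = 1.5, x = 1.5,
#'                    az = 0, ay = 0, ax = 1, length = 2, diameter = 0.6,
#'                    growth = 0)
#' lab <- voxelizeCells(cell, dim = c(20, 30, 30))
#' sum(lab == 1)  # close to the analytic spherocylinder volume in voxels
#' @export
voxelizeCells <- function(cells, dim, voxelSize = c(0.1, 0.1, 0.1),
                          origin = c(0, 0, 0)) {
  if (nrow(cells) == 0L)
    return(array(0L, dim = dim))
  h <- pmax(0, (cells$length - cells$diameter) / 2)
  r <- cells$diameter / 2
  ext <- cbind(abs(cells$az), abs(cells$ay), abs(cells$ax)) * h + r
  ctr <- as.matrix(cells[, c("z", "y", "x")])
  lo <- apply(ctr - ext, 2, min)
  hi <- apply(ctr + ext, 2, max)
  if (any(lo < origin) || any(hi > origin + dim * voxelSize))
    warning("some cells extend beyond the volume and are clipped")
  lab <- cpp_voxelize(as.matrix(cells[, c("z", "y", "x")]),
                      as.matrix(cells[, c("az", "ay", "ax")]),
                      cells$length, cells$diameter, as.integer(cells$id),
                      as.integer(dim), as.numeric(voxelSize),
                      as.numeric(origin))
  array(lab, dim = dim)
}

# expected (noiseless) emitter image for one photon per fluorophore
unitEmitterField <- function(cells, dim, cfg, origin, nEmitters) {
  field <- array(0, dim = dim)
  if (nrow(cells) > 0 && sum(nEmitters) > 0) {
    pts <- sampleEmitters(cells, nEmitters, cfg$labelingMode)
    iz <- floor((pts[, 1] - origin[1]) / cfg$voxelSize[1]) + 1L
    iy <- floor((pts[, 2] - origin[2]) / cfg$voxelSize[2]) + 1L
    ix <- floor((pts[, 3] - origin[3]) / cfg$voxelSize[3]) + 1L
    keep <- iz >= 1 & iz <= dim[1] & iy >= 1 & iy <= dim[2] &
            ix >= 1 & ix <= dim[3]
    idx <- (ix[keep] - 1L) * dim[1] * dim[2] + (iy[keep] - 1L) * dim[1] +
           iz[keep]
    cnt <- tabulate(idx, nbins = prod(dim))
    field <- array(as.numeric(cnt), dim = dim)
  }
  if (!is.null(cfg$psf)) {
    convolveFFT(field, cfg$psf)
  } else {
    sig <- cfg$psfSigma / cfg$voxelSize
    ks <- max(5L, 2L * ceiling(3 * max(sig)) + 1L)
    gaussianBlur(field, sigma = sig, ksize = ks)
  }
}

# uniform samples inside (cytosolic) or on the surface of (membrane)
# each cell's spherocylinder
sampleEmitters <- function(cells, nEmitters, mode) {
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    n <- nEmitters[i]
    if (n == 0L) next
    r <- cells$diameter[i] / 2
    h <- max(0, (cells$length[i] - cells$diameter[i]) / 2)
    a <- c(cells$az[i], cells$ay[i], cells$ax[i])
    ctr <- c(cells$z[i], cells$y[i], cells$x[i])
    # orthonormal frame (a, u, v)
    u <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- u - sum(u * a) * a
    u <- u / sqrt(sum(u^2))
    v <- c(a[2] * u[3] - a[3] * u[2], a[3] * u[1] - a[1] * u[3],
           a[1] * u[2] - a[2] * u[1])
    if (mode == "cytosolic") {
      vcyl <- pi * r^2 * 2 * h
      vsph <- 4 / 3 * pi * r^3
      inCyl <- stats::runif(n) < vcyl / (vcyl + vsph)
      ncyl <- sum(inCyl)
      t <- stats::runif(ncyl, -h, h)
      rho <- r * sqrt(stats::runif(ncyl))
      phi <- stats::runif(ncyl, 0, 2 * pi)
      pcyl <- outer(t, a) + outer(rho * cos(phi), u) + outer(rho * sin(phi), v)
      # caps: uniform in a sphere, shifted to the cap on the matching side
      nsph <- n - ncyl
      rr <- r * stats::runif(nsph)^(1 / 3)
      zz <- stats::runif(nsph, -1, 1)
      ph <- stats::runif(nsph, 0, 2 * pi)
      sq <- sqrt(pmax(0, 1 - zz^2))
      pt <- rr * cbind(zz, sq * cos(ph), sq * sin(ph))
      off <- ifelse(pt %*% a >= 0, h, -h)
      psph <- outer(as.vector(off), a) + pt
      pts <- rbind(pcyl, psph)
    } else {
      acyl <- 2 * pi * r * 2 * h
      asph <- 4 * pi * r^2
      onCyl <- stats::runif(n) < acyl / (acyl + asph)
      ncyl <- sum(onCyl)
      t <- stats::runif(ncyl, -h, h)
      phi <- stats::runif(ncyl, 0, 2 * pi)
      pcyl <- outer(t, a) + outer(r * cos(phi), u) + outer(r * sin(phi), v)
      nsph <- n - ncyl
      zz <- stats::runif(nsph, -1, 1)
      ph <- stats::runif(nsph, 0, 2 * pi)
      sq <- sqrt(pmax(0, 1 - zz^2))
      pt <- r * cbind(zz, sq * cos(ph), sq * sin(ph))
      off <- ifelse(pt %*% a >= 0, h, -h)
      psph <- outer(as.vector(off), a) + pt
      pts <- rbind(pcyl, psph)
    }
    # rotate local (z,y,x) offsets into the world frame: columns of pts
    # are already world offsets because a, u, v are world vectors
    out[[i]] <- sweep(pts, 2, ctr, "+")
  }
  do.call(rbind, out)
}

convolveFFT <- function(vol, kernel) {
  d <- dim(vol)
  kd <- dim(kernel)
  pd <- d + kd - 1L
  pv <- array(0, pd)
  pv[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- vol
  pk <- array(0, pd)
  pk[seq_len(kd[1]), seq_len(kd[2]), seq_len(kd[3])] <- kernel
  res <- Re(fft(fft(pv) * fft(pk), inverse = TRUE)) / prod(pd)
  ctr <- (kd - 1L) %/% 2L
  res[ctr[1] + seq_len(d[1]), ctr[2] + seq_len(d[2]), ctr[3] + seq_len(d[3])]
}

#' Render a 3D fluorescence image of a simulated biofilm
#'
#' Emitters are sampled per cell (Poisson-distributed counts around
#' \code{fluorophoresPerCell}), binned into the voxel grid, convolved with
#' the PSF and scaled to photons; the constant background is added and the
#' image is corrupted by Poisson shot noise on the summed signal plus
#' background, followed by zero-mean Gaussian read noise, clipped at 0.
#' When \code{cfg$targetSBR} is set, the photon scale is solved in closed
#' form so the noiseless image hits the requested signal-to-background
#' ratio.
#'
#' @param labels label volume matching \code{cells} (used for SBR
#'   calibration; never modified).
#' @param cells colony frame data.frame.
#' @param cfg a [renderConfig()].
#' @param origin volume origin in micrometres.
#' @param seed integer RNG seed; identical seeds give identical images.
#' @return numeric intensity volume; attributes \code{photonsPerFluorophore}
#'   (the scale actually used) and \code{sbr} (noiseless SBR).
#' @export
renderBiofilm <- function(labels, cells, cfg = renderConfig(),
                          origin = c(0, 0, 0), seed = 1L) {
  assertLabels(labels)
  d <- dim(labels)
  withSeed(seed, {
    nEm <- stats::rpois(nrow(cells), cfg$fluorophoresPerCell)
    unit <- unitEmitterField(cells, d, cfg, origin, nEm)
    alpha <- cfg$photonsPerFluorophore
    sbr <- NA_real_
    if (sum(nEm) > 0) {
      fg <- labels > 0
      shell <- nearBackgroundMask(labels, shell = 3L)
      mf <- mean(unit[fg])
      mb <- mean(unit[shell])
      if (!is.null(cfg$targetSBR)) {
        S <- cfg$targetSBR
        denom <- mf - S * mb
        if (denom <= 0)
          stop("requested SBR is unreachable with this PSF/geometry")
        alpha <- cfg$backgroundMean * (S - 1) / denom
      }
      sbr <- (cfg$backgroundMean + alpha * mf) /
             (cfg$backgroundMean + alpha * mb)
    }
    noiseless <- alpha * unit + cfg$backgroundMean
    img <- stats::rpois(length(noiseless), noiseless) +
           stats::rnorm(length(noiseless), 0, cfg$readNoise)
    img <- array(pmax(img, 0), dim = d)
    attr(img, "photonsPerFluorophore") <- alpha
    attr(img, "sbr") <- sbr
    img
  })
}

# background voxels within `shell` voxels of any cell
nearBackgroundMask <- function(labels, shell = 3L) {
  dist2fg <- edtSquared(labels == 0)  # distance to nearest foreground
  labels == 0 & dist2fg <= shell^2
}

#' Signal-to-background ratio of an image given its label volume
#'
#' Mean intensity over cell (foreground) voxels divided by the mean
#' intensity over background voxels lying within \code{shell} voxels of
#' any cell, emulating manually selected near-cell background regions.
#'
#' @param image intensity volume.
#' @param labels label volume of the same shape (must contain cells).
#' @param shell background shell width in voxels.
#' @return the SBR (positive scalar).
#' @export
estimateSBR <- function(image, labels, shell = 3L) {
  assertVolume(image)
  assertLabels(labels)
  stopifnot(identical(dim(image), dim(labels)))
  if (!any(labels > 0)) stop("labels contain no cells")
  bg <- nearBackgroundMask(labels, shell)
  if (!any(bg)) stop("empty background shell")
  mean(image[labels > 0]) / mean(image[bg])
}

#' Local cell density from the densest image tiles
#'
#' Partitions the volume into non-overlapping 3D tiles (partial edge
#' tiles are dropped), computes the cell volume fraction of each tile and
#' reports the mean over the 10 densest tiles (or all tiles, if fewer).
#'
#' @param labels label volume.
#' @param tileShape tile dimensions in voxels, ZYX; the default
#'   c(8, 64, 64) corresponds to 64 x 64 x 8 voxel (XYZ) tiles.
#' @return list with \code{tileShape}, \code{perTileDensity} and
#'   \code{reportedDensity}.
#' @export
localDensity <- function(labels, tileShape = c(8L, 64L, 64L)) {
  assertLabels(labels)
  d <- dim(labels)
  nt <- d %/% tileShape
  if (any(nt < 1L)) stop("volume smaller than one tile")
  dens <- numeric(prod(nt))
  i <- 1L
  for (tx in seq_len(nt[3])) for (ty in seq_len(nt[2])) for (tz in seq_len(nt[1])) {
    zi <- (tz - 1L) * tileShape[1] + seq_len(tileShape[1])
    yi <- (ty - 1L) * tileShape[2] + seq_len(tileShape[2])
    xi <- (tx - 1L) * tileShape[3] + seq_len(tileShape[3])
    dens[i] <- mean(labels[zi, yi, xi] > 0)
    i <- i + 1L
  }
  k <- min(10L, length(dens))
  list(tileShape = tileShape, perTileDensity = dens,
       reportedDensity = mean(sort(dens, decreasing = TRUE)[seq_len(k)]))
}
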