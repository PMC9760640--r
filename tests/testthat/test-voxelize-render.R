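# voxelization against the analytic spherocylinder volume; rendering
# noise model; SBR estimation; local density

test_that("voxel count approaches the analytic spherocylinder volume", {
  cell <- cellRow(1, c(1.03, 1.07, 1.51), c(0, 0, 1), 2, 0.6)
  va <- pi * 0.3^2 * (2 - 0.6) + 4 / 3 * pi * 0.3^3
  lab <- voxelizeCells(cell, dim = c(21, 21, 31), voxelSize = rep(0.1, 3))
  expect_lt(abs(sum(lab > 0) * 0.1^3 - va) / va, 0.05)
})

test_that("voxelization error shrinks as the voxel size decreases", {
  # grid-corner-aligned placement: the worst case for digitization bias
  err <- sapply(c(0.1, 0.05), function(vs) {
    cell <- cellRow(1, c(1.5, 1.5, 2), c(0, 0, 1), 2, 0.6)
    dims <- ceiling(c(3, 3, 4) / vs)
    lab <- voxelizeCells(cell, dim = dims, voxelSize = rep(vs, 3))
    va <- pi * 0.3^2 * (2 - 0.6) + 4 / 3 * pi * 0.3^3
    abs(sum(lab > 0) * vs^3 - va) / va
  })
  expect_lt(err[2], err[1])
})

test_that("empty and disjoint cell lists voxelize as expected", {
  none <- cellRow(1, c(1, 1, 1), c(0, 0, 1), 2, 0.6)[0, ]
  expect_true(all(voxelizeCells(none, dim = c(8, 8, 8)) == 0))
  two <- rbind(cellRow(1, c(1, 1, 1), c(0, 0, 1), 1.4, 0.6),
               cellRow(2, c(1, 2.6, 1), c(0, 0, 1), 1.4, 0.6))
  lab <- voxelizeCells(two, dim = c(20, 36, 24))
  expect_setequal(unique(as.vector(lab[lab > 0])), c(1L, 2L))
})

test_that("a pure background render matches the Poisson mean", {
  empty <- array(0L, c(40, 50, 50))
  cfg <- renderConfig(fluorophoresPerCell = 0, backgroundMean = 100,
                      readNoise = 0)
  img <- renderBiofilm(empty, cellRow(1, c(1, 1, 1), c(0, 0, 1), 2, 1)[0, ],
                       cfg, seed = 4)
  se <- sqrt(100 / length(img))
  expect_lt(abs(mean(img) - 100), 3 * se)
})

test_that("background variance is the Poisson plus read-noise sum", {
  empty <- array(0L, c(48, 50, 50))  # 120k voxels
  cfg <- renderConfig(fluorophoresPerCell = 0, backgroundMean = 100,
                      readNoise = 3.04)
  img <- renderBiofilm(empty, cellRow(1, c(1, 1, 1), c(0, 0, 1), 2, 1)[0, ],
                       cfg, seed = 11)
  v <- var(as.vector(img))
  expected <- 100 + 3.04^2
  seVar <- expected * sqrt(2 / (length(img) - 1))
  expect_lt(abs(v - expected), 3 * seVar)
})

test_that("rendering is deterministic and never alters the labels", {
  fr <- growColony(nSteps = 16, nSeedCells = 1, seed = 2)
  cells <- fr[[length(fr)]]
  geom <- colonyGeometry(cells)
  lab <- voxelizeCells(cells, geom$dim, origin = geom$origin)
  labCopy <- lab + 0L
  a <- renderBiofilm(lab, cells, renderConfig(), geom$origin, seed = 5)
  b <- renderBiofilm(lab, cells, renderConfig(), geom$origin, seed = 5)
  expect_identical(a, b)
  expect_identical(lab, labCopy)
})

test_that("a non-normalized PSF is rejected", {
  psf <- array(1, c(3, 3, 3))
  expect_error(renderConfig(psf = psf), "normalized")
})

test_that("the requested SBR is reached by the closed-form calibration", {
  fr <- growColony(nSteps = 20, nSeedCells = 2, seed = 6)
  cells <- fr[[length(fr)]]
  geom <- colonyGeometry(cells)
  lab <- voxelizeCells(cells, geom$dim, origin = geom$origin)
  img <- renderBiofilm(lab, cells, renderConfig(targetSBR = 1.34),
                       geom$origin, seed = 7)
  expect_equal(attr(img, "sbr"), 1.34, tolerance = 1e-6)
  expect_equal(estimateSBR(img, lab), 1.34, tolerance = 0.02)
})

test_that("SBR is the foreground/background ratio and is scale invariant", {
  lab <- blockVolume(c(10, 12, 12), 4:7, 4:9, 4:9)
  img <- array(100, dim(lab))
  img[lab > 0] <- 134
  expect_equal(estimateSBR(img, lab), 1.34)
  expect_equal(estimateSBR(array(100, dim(lab)), lab), 1)
  expect_equal(estimateSBR(img * 2, lab), estimateSBR(img, lab))
})

test_that("local density reports the mean of the ten densest tiles", {
  tile <- c(4L, 8L, 8L)
  lab <- array(0L, c(8, 32, 32))   # 2 x 4 x 4 = 32 tiles
  expect_equal(localDensity(lab, tile)$reportedDensity, 0)
  full <- array(1L, c(8, 32, 32))
  expect_equal(localDensity(full, tile)$reportedDensity, 1)
  # exactly one half-full tile among 32
  half <- array(0L, c(8, 32, 32))
  half[1:2, 1:8, 1:8] <- 1L
  dens <- localDensity(half, tile)
  expect_equal(max(dens$perTileDensity), 0.5)
  expect_equal(dens$reportedDensity, 0.05)
})
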