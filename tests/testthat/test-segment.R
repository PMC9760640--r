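# Otsu thresholds, the oracle predictor contract, and watershed
# segmentation from representation pairs

test_that("Otsu thresholds classify well-separated modes correctly", {
  set.seed(10)
  lo <- rnorm(4000, 10, 1)
  hi <- rnorm(4000, 60, 2)
  th <- otsuThresholds(c(lo, hi), 2)
  expect_true(all(lo < th) && all(hi >= th))
  a <- rnorm(3000, 0, .5)
  b <- rnorm(3000, 20, .5)
  c3 <- rnorm(3000, 50, .5)
  th3 <- otsuThresholds(c(a, b, c3), 3)
  expect_length(th3, 2)
  expect_true(all(a < th3[1]) && all(b >= th3[1]) && all(b < th3[2]) &&
              all(c3 >= th3[2]))
  expect_equal(otsuThresholds(rep(5, 10), 3), c(5, 5))
})

test_that("the oracle predictor replays the training representations", {
  lab <- array(0L, c(10, 12, 12))
  lab[3:7, 3:8, 3:8] <- 1L
  pred <- oraclePredictor(lab)
  img <- array(0, dim(lab))
  out <- pred@predictFun(img)
  ref <- makeTrainingPair(lab)
  expect_identical(distRep(out), distRep(ref))
  expect_identical(boundaryRep(out), boundaryRep(ref))
  empty <- oraclePredictor(array(0L, c(4, 4, 4)))
  o <- empty@predictFun(array(0, c(4, 4, 4)))
  expect_true(all(distRep(o) == 0))
})

test_that("two separated balls segment into two high-IoU objects", {
  lab <- ballVolume(c(24, 24, 40), c(12, 12, 12), 6)
  lab <- ballVolume(c(24, 24, 40), c(12, 12, 29), 6, label = 2L, base = lab)
  seg <- segmentImage(array(0, dim(lab)), oraclePredictor(lab))
  expect_equal(length(unique(seg[seg > 0])), 2L)
  m <- matchObjects(seg, lab)
  expect_equal(nrow(matchedPairs(m)), 2L)
  expect_true(all(matchedPairs(m)$iou >= 0.9))
})

test_that("all-zero representations yield an empty labeling", {
  pair <- new("RepresentationPair", distRep = array(0, c(6, 6, 6)),
              boundaryRep = array(0, c(6, 6, 6)))
  expect_true(all(segmentRepresentation(pair) == 0))
})

test_that("two touching rods are split along the boundary ridge", {
  side <- rbind(cellRow(1, c(1.0, 1.0, 1.6), c(0, 0, 1), 2.4, 0.8),
                cellRow(2, c(1.0, 1.82, 1.6), c(0, 0, 1), 2.4, 0.8))
  lab <- voxelizeCells(side, dim = c(20, 29, 32))
  expect_equal(length(unique(lab[lab > 0])), 2L)
  seg <- segmentRepresentation(makeTrainingPair(lab))
  expect_equal(length(unique(seg[seg > 0])), 2L)
  m <- matchObjects(seg, lab)
  expect_equal(nrow(matchedPairs(m)), 2L)
})

test_that("labels partition the mask and seed count bounds object count", {
  set.seed(8)
  fr <- growColony(nSteps = 24, nSeedCells = 2, seed = 8)
  cells <- fr[[length(fr)]]
  geom <- colonyGeometry(cells)
  lab <- voxelizeCells(cells, geom$dim, origin = geom$origin)
  pair <- makeTrainingPair(lab)
  seg <- segmentRepresentation(pair)
  # disjoint cover: every labelled voxel has exactly one label by
  # construction; objects respect the min size
  sizes <- tabulate(seg[seg > 0])
  expect_true(all(sizes[sizes > 0] >= 30))
  # seed monotonicity: raising minSeedVoxels never increases object count
  n1 <- max(segmentRepresentation(pair, postProcessConfig(minSeedVoxels = 1)))
  n2 <- max(segmentRepresentation(pair, postProcessConfig(minSeedVoxels = 20)))
  n3 <- max(segmentRepresentation(pair, postProcessConfig(minSeedVoxels = 200)))
  expect_true(n1 >= n2 && n2 >= n3)
})

test_that("label permutation of the oracle input relabels the output only", {
  lab <- ballVolume(c(20, 20, 34), c(10, 10, 10), 5)
  lab <- ballVolume(c(20, 20, 34), c(10, 10, 25), 5, label = 2L, base = lab)
  perm <- lab
  perm[lab == 1L] <- 9L
  perm[lab == 2L] <- 4L
  s1 <- segmentRepresentation(makeTrainingPair(lab))
  s2 <- segmentRepresentation(makeTrainingPair(perm))
  expect_equal(s1 > 0, s2 > 0)
  m <- matchObjects(s1, s2)
  expect_equal(nrow(matchedPairs(m)), max(s1))
  expect_true(all(matchedPairs(m)$iou == 1))
})

test_that("segmentImage composes predictor and post-processing", {
  lab <- ballVolume(c(16, 16, 16), c(8, 8, 8), 5)
  pred <- oraclePredictor(lab)
  img <- array(runif(length(lab)), dim(lab))
  expect_identical(segmentImage(img, pred),
                   segmentRepresentation(makeTrainingPair(lab)))
  bad <- asPredictor("broken", function(image) image)
  expect_error(segmentImage(img, bad), "RepresentationPair")
})
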