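# object matching, CA, SSA, SBF1: formulas, worked example, oracle
# equivalence, symmetry and monotonicity

test_that("identical volumes match perfectly", {
  set.seed(31)
  lab <- randomBlobVolume(c(12, 14, 16), nBlobs = 3L)
  m <- matchObjects(lab, lab)
  expect_equal(nrow(matchedPairs(m)), length(unique(lab[lab > 0])))
  expect_true(all(matchedPairs(m)$iou == 1))
  expect_equal(countingAccuracy(m), 1)
  expect_equal(ssa(m), 1)
  expect_equal(sbf1(lab, lab, m), 1)
})

test_that("an empty prediction yields only false negatives", {
  ref <- ballVolume(c(10, 10, 10), c(5, 5, 5), 3)
  m <- matchObjects(array(0L, dim(ref)), ref)
  expect_equal(nrow(matchedPairs(m)), 0L)
  expect_equal(length(unmatchedRef(m)), 1L)
  expect_equal(countingAccuracy(m), 0)
  expect_error(ssa(m), "no matched")
  expect_error(sbf1(array(0L, dim(ref)), ref, m), "no matched")
})

test_that("counting accuracy follows TP/(TP+FP+FN)", {
  # 8 matched balls, 1 extra prediction, 1 extra reference
  d <- c(8, 20, 100)
  pred <- array(0L, d)
  ref <- array(0L, d)
  for (i in 1:9) pred <- ballVolume(d, c(4, 10, 10 * i - 4), 3,
                                    label = as.integer(i), base = pred)
  for (i in 1:8) ref <- ballVolume(d, c(4, 10, 10 * i - 4), 3,
                                   label = as.integer(i), base = ref)
  ref <- ballVolume(d, c(4, 10, 96), 3, label = 9L, base = ref)
  m <- matchObjects(pred, ref)
  expect_equal(nrow(matchedPairs(m)), 8L)
  expect_equal(countingAccuracy(m), 0.8)
})

test_that("greedy matching equals the exhaustive optimum on random fixtures", {
  set.seed(12)
  for (rep in 1:4) {
    d <- c(10, 24, 24)
    pred <- array(0L, d)
    ref <- array(0L, d)
    centres <- expand.grid(y = c(6, 18), x = c(6, 18))
    for (i in seq_len(nrow(centres))) {
      pred <- ballVolume(d, c(5, centres$y[i], centres$x[i]), 3,
                         label = as.integer(i), base = pred)
      jit <- sample(-2:2, 2, replace = TRUE)
      ref <- ballVolume(d, c(5, centres$y[i] + jit[1], centres$x[i] + jit[2]),
                        3, label = as.integer(i), base = ref)
    }
    m <- matchObjects(pred, ref, metricsConfig(iouThreshold = 0.1))
    # exhaustive: all bijections between pred and ref ids
    ids <- seq_len(nrow(centres))
    iouOf <- function(p, r) {
      inter <- sum(pred == p & ref == r)
      if (inter == 0) return(0)
      inter / sum(pred == p | ref == r)
    }
    iouM <- outer(ids, ids, Vectorize(iouOf))
    best <- -Inf
    for (perm in asplit(allPermutations(ids), 1)) {
      v <- iouM[cbind(ids, perm)]
      best <- max(best, sum(v[v >= 0.1]))
    }
    expect_equal(sum(matchedPairs(m)$iou), best, tolerance = 1e-12)
  }
})

test_that("the disk-in-square worked example reproduces the printed values", {
  fx <- diskSquareFixture()
  m <- matchObjects(fx$pred, fx$ref, metricsConfig(iouThreshold = 0.5))
  expect_equal(nrow(matchedPairs(m)), 1L)
  expect_equal(matchedPairs(m)$iou, 0.8, tolerance = 0.02)
  expect_equal(ssa(m), 0.79, tolerance = 1e-9)
  expect_equal(sbf1(fx$pred, fx$ref, m), 0.67, tolerance = 0.02)
})

test_that("SSA is the mean of the matched IoU values", {
  m <- new("MatchResult",
           pairs = data.frame(pred = 1:2, ref = 1:2, iou = c(0.6, 0.8)),
           unmatchedPred = integer(0), unmatchedRef = integer(0),
           iouThreshold = 0.5)
  expect_equal(ssa(m), 0.7)
})

test_that("a one-voxel shift stays within the boundary tolerance", {
  d <- c(8, 16, 16)
  a <- blockVolume(d, 3:6, 4:9, 4:9)
  b <- blockVolume(d, 3:6, 5:10, 4:9)
  m <- matchObjects(a, b, metricsConfig(iouThreshold = 0.3))
  expect_equal(sbf1(a, b, m), 1)
})

test_that("SSA and SBF1 are symmetric in prediction and reference", {
  set.seed(77)
  d <- c(10, 20, 20)
  a <- ballVolume(d, c(5, 9, 9), 4)
  a <- ballVolume(d, c(5, 15, 15), 3, label = 2L, base = a)
  b <- ballVolume(d, c(5, 10, 9), 4)
  b <- ballVolume(d, c(6, 15, 14), 3, label = 2L, base = b)
  m1 <- matchObjects(a, b)
  m2 <- matchObjects(b, a)
  expect_equal(ssa(m1), ssa(m2))
  expect_equal(sbf1(a, b, m1), sbf1(b, a, m2))
})

test_that("CA is non-increasing in the IoU threshold and metrics are bounded", {
  set.seed(19)
  fr <- growColony(nSteps = 20, nSeedCells = 2, seed = 19)
  cells <- fr[[length(fr)]]
  geom <- colonyGeometry(cells)
  lab <- voxelizeCells(cells, geom$dim, origin = geom$origin)
  seg <- segmentRepresentation(makeTrainingPair(lab))
  rep <- segmentationReport(seg, lab)
  ca <- rep$caGrid$ca
  expect_true(all(diff(ca) <= 1e-12))
  expect_true(all(ca >= 0 & ca <= 1))
  expect_true(rep$ssa >= 0 && rep$ssa <= 1)
  expect_true(rep$sbf1 >= 0 && rep$sbf1 <= 1)
})
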