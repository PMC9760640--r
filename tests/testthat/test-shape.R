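# shape features, convex hull solidity, PCA projection, rod classifier

test_that("a digital ball is isotropic with solidity near 1", {
  sph <- ballVolume(c(17, 17, 17), c(9, 9, 9), 6)
  f <- shapeFeatures(sph)
  expect_equal(f$minorRatio, 1, tolerance = 0.05)
  expect_equal(f$majorAxis / f$minorAxisShort, 1, tolerance = 0.05)
  expect_gte(f$solidity, 0.95)
})

test_that("a voxelized spherocylinder is a high-solidity rod", {
  cell <- cellRow(1, c(1.03, 1.07, 1.51), c(0, 0, 1), 2, 0.6)
  rod <- voxelizeCells(cell, dim = c(21, 21, 31))
  f <- shapeFeatures(rod)
  expect_gte(f$solidity, 0.9)
  expect_gt(f$majorAxis, f$minorAxisLong)
  expect_equal(classifyRod(f), "rod")
})

test_that("an L-shaped merged pair loses solidity and classifies odd", {
  # arms joined end to end at a corner
  Lpair <- rbind(cellRow(1, c(1.0, 0.9, 1.9), c(0, 0, 1), 2, 0.6),
                 cellRow(1, c(1.0, 1.9, 0.9), c(0, 1, 0), 2, 0.6))
  Lv <- voxelizeCells(Lpair, dim = c(21, 31, 31))
  fL <- shapeFeatures(Lv)
  rod <- voxelizeCells(cellRow(1, c(1.03, 1.07, 1.51), c(0, 0, 1), 2, 0.6),
                       dim = c(21, 21, 31))
  fR <- shapeFeatures(rod)
  expect_lt(fL$solidity, fR$solidity)
  expect_equal(classifyRod(fL), "odd")
})

test_that("hull volumes match closed forms on exact polyhedra", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(biofilm3d:::cpp_hull_volume(cube), 1)
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(biofilm3d:::cpp_hull_volume(tet), 1 / 6)
  oct <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  expect_equal(biofilm3d:::cpp_hull_volume(oct), 4 / 3)
  # interior points must not change the hull
  set.seed(2)
  inner <- matrix(runif(60, 0.2, 0.8), ncol = 3)
  expect_equal(biofilm3d:::cpp_hull_volume(rbind(cube, inner)), 1)
})

test_that("features are invariant under translation and flips", {
  cell <- cellRow(1, c(0.9, 1.1, 1.4), c(0, 0.6, 0.8), 1.8, 0.6)
  lab <- voxelizeCells(cell, dim = c(20, 26, 30))
  f0 <- shapeFeatures(lab)
  shifted <- array(0L, c(24, 30, 34))
  shifted[3:22, 3:28, 3:32] <- lab
  f1 <- shapeFeatures(shifted)
  flipped <- lab[dim(lab)[1]:1, , ]
  f2 <- shapeFeatures(flipped)
  for (col in c("volume", "solidity", "majorAxis", "minorAxisLong")) {
    expect_equal(f1[[col]], f0[[col]], tolerance = 1e-9)
    expect_equal(f2[[col]], f0[[col]], tolerance = 1e-9)
  }
})

test_that("PCA projection centres scores and ranks variance", {
  set.seed(6)
  n <- 40
  base <- rnorm(n, 0, 4)
  feats <- data.frame(id = 1:n,
                      volume = 100 + 10 * base + rnorm(n),
                      solidity = 0.9 + 0.01 * base + rnorm(n, 0, 0.005),
                      majorAxis = 20 + rnorm(n),
                      minorAxisLong = 6 + rnorm(n, 0, 0.5),
                      minorAxisShort = 6 + rnorm(n, 0, 0.5),
                      minorRatio = 1 + abs(rnorm(n, 0, 0.05)))
  feats$minorRatioInv <- 1 / feats$minorRatio
  pr <- pcaProject(feats)
  expect_equal(mean(pr$scores$PC1), 0, tolerance = 1e-9)
  expect_equal(mean(pr$scores$PC2), 0, tolerance = 1e-9)
  expect_gt(pr$explained[["PC1"]], pr$explained[["PC2"]])
  # duplicated rows project identically
  dup <- rbind(feats, feats[1, ])
  pr2 <- pcaProject(dup)
  expect_equal(pr2$scores$PC1[n + 1], pr2$scores$PC1[1])
  # constant columns are dropped with a warning
  feats$const <- 1
  expect_warning(pcaProject(feats), "constant")
})

test_that("rod classification on oracle-segmented colonies is predominantly rod", {
  fr <- growColony(nSteps = 26, nSeedCells = 2, seed = 13)
  cells <- fr[[length(fr)]]
  geom <- colonyGeometry(cells)
  lab <- voxelizeCells(cells, geom$dim, origin = geom$origin)
  seg <- segmentRepresentation(makeTrainingPair(lab))
  cls <- classifyRod(shapeFeatures(seg))
  expect_gte(mean(cls == "rod"), 0.9)
  expect_identical(classifyRod(shapeFeatures(lab)[0, ]), character(0))
})
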