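# nearest-neighbour linking, division detection, lineage construction,
# relative movement

test_that("a static colony links to itself identically", {
  v <- rbind(vRow(1, 1, 0, 0, 0), vRow(1, 2, 0, 2, 0), vRow(1, 3, 0, 0, 2))
  w <- v
  w$frame <- 2L
  links <- linkFrames(v, w)
  expect_equal(links$fromId, links$toId)
  expect_equal(nrow(links), 3L)
  expect_true(all(links$distance == 0))
})

test_that("cells beyond the maximum link distance stay unlinked", {
  a <- vRow(1, 1, 0, 0, 0)
  b <- vRow(2, 1, 0, 0, 1.5)
  expect_equal(nrow(linkFrames(a, b, trackingConfig(maxLinkDistance = 1))), 0L)
  expect_equal(nrow(linkFrames(a, b, trackingConfig(maxLinkDistance = 2))), 1L)
})

test_that("greedy linking equals closest-pairs-first enumeration", {
  set.seed(14)
  for (rep in 1:5) {
    a <- do.call(rbind, lapply(1:3, function(i)
      vRow(1, i, runif(1), runif(1), runif(1))))
    b <- do.call(rbind, lapply(1:3, function(i)
      vRow(2, i, runif(1), runif(1), runif(1))))
    links <- linkFrames(a, b, trackingConfig(maxLinkDistance = 2))
    # brute force
    dd <- as.matrix(dist(rbind(as.matrix(a[, c("z", "y", "x")]),
                               as.matrix(b[, c("z", "y", "x")]))))[1:3, 4:6]
    cand <- which(dd <= 2, arr.ind = TRUE)
    ord <- order(dd[cand], a$id[cand[, 1]], b$id[cand[, 2]])
    usedA <- usedB <- logical(3)
    exp <- NULL
    for (i in ord) {
      p <- cand[i, 1]; q <- cand[i, 2]
      if (!usedA[p] && !usedB[q]) {
        usedA[p] <- usedB[q] <- TRUE
        exp <- rbind(exp, data.frame(fromId = a$id[p], toId = b$id[q]))
      }
    }
    links <- links[order(links$fromId), c("fromId", "toId")]
    expect_equal(links, exp[order(exp$fromId), ], ignore_attr = TRUE)
  }
})

test_that("a division yields two parent-daughter edges from the parent", {
  parent <- vRow(1, 7, 0, 0, 0, volume = 2.1, length = 3)
  daughters <- rbind(vRow(2, 8, 0, 0, 0.7, volume = 0.9, length = 1.5),
                     vRow(2, 9, 0, 0, -0.7, volume = 0.9, length = 1.5))
  links <- linkFrames(parent, daughters)
  div <- detectDivisions(parent, daughters, links)
  expect_equal(nrow(div$track), 0L)
  expect_equal(nrow(div$parentDaughter), 2L)
  expect_equal(div$parentDaughter$fromId, c(7, 7))
  expect_setequal(div$parentDaughter$toId, c(8, 9))
})

test_that("a neighbour violating the size ratios is not adopted", {
  a <- rbind(vRow(1, 1, 0, 0, 0, volume = 1.0, length = 2),
             vRow(1, 2, 0, 0, 3, volume = 1.0, length = 2))
  b <- rbind(vRow(2, 1, 0, 0, 0, volume = 1.0, length = 2),
             vRow(2, 2, 0, 0, 3, volume = 1.0, length = 2),
             vRow(2, 3, 0, 0.5, 0.3, volume = 0.9, length = 1.9))
  links <- linkFrames(a, b)
  div <- detectDivisions(a, b, links)
  # volume ratio 1.0/0.9 < 1.5: no parent qualifies
  expect_equal(nrow(div$parentDaughter), 0L)
  expect_equal(nrow(div$track), 2L)
})

test_that("a single static cell over five frames gives four track edges", {
  frames <- lapply(1:5, function(t) vRow(t, 1, 0, 0, 0))
  g <- buildLineage(frames)
  e <- lineageEdges(g)
  expect_equal(nrow(e), 4L)
  expect_true(all(e$type == "track"))
  expect_true(validObject(g))
})

test_that("tracking ground-truth centroids recovers the simulated lineage", {
  fr <- growColony(nSteps = 22, nSeedCells = 3, seed = 21)
  gt <- colonyLineage(fr)
  tabs <- split(lineageVertices(gt), lineageVertices(gt)$frame)
  tabs <- lapply(tabs, function(x) { x$frame <- NULL; x })
  est <- buildLineage(tabs, trackingConfig(maxLinkDistance = 1))
  expect_true(validObject(est))
  tr <- traScores(est, gt)
  expect_gte(tr$traEdge, 0.95)
})

test_that("a dispersing daughter terminates its track", {
  # parent divides at t1 -> t2; one daughter disappears at t3
  f1 <- vRow(1, 1, 0, 0, 0, volume = 2, length = 3)
  f2 <- rbind(vRow(2, 2, 0, 0, 0.7, volume = 0.9, length = 1.5),
              vRow(2, 3, 0, 0, -0.7, volume = 0.9, length = 1.5))
  f3 <- vRow(3, 2, 0, 0, 0.75, volume = 1.0, length = 1.6)
  g <- buildLineage(list(f1, f2, f3))
  e <- lineageEdges(g)
  expect_equal(sum(e$type == "parent-daughter"), 2L)
  expect_equal(sum(e$fromFrame == 2 & e$type == "track"), 1L)
  expect_false(any(e$fromFrame == 2 & e$fromId == 3))
})

test_that("relative movement is 0 for static cells and 1 at neighbour swap", {
  # static pair
  frames <- lapply(1:3, function(t)
    rbind(vRow(t, 1, 0, 0, 0), vRow(t, 2, 0, 0, 2)))
  g <- buildLineage(frames, trackingConfig(maxLinkDistance = 1))
  expect_equal(relativeMovement(g)$mean, 0)
  # a cell lands exactly on its static neighbour's position
  v1 <- rbind(vRow(1, 1, 0, 0, 0), vRow(1, 2, 0, 0, 2))
  v2 <- rbind(vRow(2, 1, 0, 0, 2), vRow(2, 2, 0, 0, 2))
  gm <- makeGraph(rbind(v1, v2),
                  data.frame(fromFrame = 1L, fromId = 1:2, toFrame = 2L,
                             toId = 1:2, type = "track"))
  rm <- relativeMovement(gm)
  expect_equal(rm$rm$rm[rm$rm$id == 1], 1)
})

test_that("relative movement matches a brute-force computation", {
  set.seed(99)
  n <- 20
  v1 <- do.call(rbind, lapply(1:n, function(i)
    vRow(1, i, runif(1, 0, 5), runif(1, 0, 5), runif(1, 0, 5))))
  v2 <- v1
  v2$frame <- 2L
  v2$z <- v2$z + rnorm(n, 0, 0.05)
  v2$y <- v2$y + rnorm(n, 0, 0.05)
  v2$x <- v2$x + rnorm(n, 0, 0.05)
  g <- makeGraph(rbind(v1, v2),
                 data.frame(fromFrame = 1L, fromId = 1:n, toFrame = 2L,
                            toId = 1:n, type = "track"))
  rm <- relativeMovement(g)
  for (i in seq_len(n)) {
    num <- sqrt(sum((v1[i, c("z", "y", "x")] - v2[i, c("z", "y", "x")])^2))
    den <- min(sqrt(colSums((t(as.matrix(v2[-i, c("z", "y", "x")])) -
                             as.numeric(v1[i, c("z", "y", "x")]))^2)))
    expect_equal(rm$rm$rm[rm$rm$id == i], num / den, tolerance = 1e-12)
  }
})
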