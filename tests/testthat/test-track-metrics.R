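# AOGM counting, detection matching, TRA scores

test_that("identical frames give a clean bijection", {
  set.seed(55)
  lab <- randomBlobVolume(c(10, 14, 14), nBlobs = 3L)
  mv <- matchVertices(list(lab), list(lab))
  expect_equal(mv$NS, 0L)
  expect_equal(mv$FN, 0L)
  expect_equal(mv$FP, 0L)
  expect_true(all(mv$correspondence$gtId == mv$correspondence$estId))
})

test_that("a merged detection covering two cells counts one missed split", {
  d <- c(8, 12, 24)
  gt <- blockVolume(d, 3:6, 3:10, 3:10, 1L)
  gt <- blockVolume(d, 3:6, 3:10, 13:20, 2L, base = gt)
  est <- blockVolume(d, 3:6, 3:10, 3:20, 1L)
  mv <- matchVertices(list(est), list(gt))
  expect_equal(mv$NS, 1L)
  expect_equal(mv$FN, 0L)
  expect_equal(mv$FP, 0L)
})

test_that("partial overlaps follow the >50 percent coverage rule", {
  d <- c(6, 10, 30)
  gt <- blockVolume(d, 2:5, 2:9, 2:11, 1L)       # 4*8*10 = 320 voxels
  gt <- blockVolume(d, 2:5, 2:9, 16:25, 2L, base = gt)
  est <- blockVolume(d, 2:5, 2:9, 2:7, 1L)       # covers 6/10 of gt 1
  est <- blockVolume(d, 2:5, 2:9, 18:29, 2L, base = est) # 8/10 of gt 2
  mv <- matchVertices(list(est), list(gt))
  expect_equal(mv$correspondence$estId, c(1L, 2L))
  est2 <- blockVolume(d, 2:5, 2:9, 2:5, 1L)      # covers only 4/10
  mv2 <- matchVertices(list(est2), list(gt))
  expect_equal(mv2$FN, 2L)
  expect_equal(mv2$FP, 1L)
})

test_that("perfect and empty estimates bracket the TRA range", {
  fr <- growColony(nSteps = 15, nSeedCells = 2, seed = 31)
  gt <- colonyLineage(fr)
  tr <- traScores(gt, gt)
  expect_equal(tr$traEdge, 1)
  expect_equal(tr$traFull, 1)
  empty <- makeGraph(lineageVertices(gt)[0, ])
  tr0 <- traScores(empty, gt)
  expect_equal(tr0$traFull, 0)
  expect_equal(tr0$traEdge, 0)
  expect_error(aogm(gt, makeGraph(lineageVertices(gt)[0, ])), "empty reference")
})

test_that("one missing edge among ten gives TRA_edge 0.9", {
  verts <- do.call(rbind, lapply(1:11, function(t) vRow(t, 1, x = t * 0.1)))
  edges <- data.frame(fromFrame = 1:10, fromId = 1L, toFrame = 2:11,
                      toId = 1L, type = "track")
  gt <- makeGraph(verts, edges)
  est <- makeGraph(verts, edges[-4, ])
  tr <- traScores(est, gt)
  expect_equal(tr$traEdge, 1 - 1 / 10)
  counts <- aogmCounts(tr$edgeReport)
  expect_equal(counts[["EA"]], 1)
  expect_equal(counts[["ED"]], 0)
})

test_that("semantics flips are counted as edge corrections", {
  verts <- rbind(vRow(1, 1), vRow(1, 2),
                 vRow(2, 1), vRow(2, 2),
                 vRow(3, 1), vRow(3, 2))
  edges <- data.frame(fromFrame = c(1, 1, 2, 2), fromId = c(1, 2, 1, 2),
                      toFrame = c(2, 2, 3, 3), toId = c(1, 2, 1, 2),
                      type = "track")
  gt <- makeGraph(verts, edges)
  flipped <- edges
  flipped$type[c(1, 3)] <- "parent-daughter"
  est <- makeGraph(verts, flipped)
  r <- aogm(est, gt)
  expect_equal(aogmCounts(r)[["EC"]], 2)
  expect_equal(aogmCounts(r)[["EA"]], 0)
  expect_equal(aogmCounts(r)[["ED"]], 0)
})

test_that("counted operations equal the independent oracle on random graphs", {
  for (seed in 1:25) {
    p <- randomGraphPair(seed)
    r <- aogm(p$est, p$gt)
    expect_equal(aogmCounts(r), oracleAOGM(p$est, p$gt),
                 ignore_attr = FALSE, tolerance = 0)
  }
})

test_that("TRA lies in [0,1] and degrades when an erroneous edge is added", {
  p <- randomGraphPair(101)
  base <- traScores(p$est, p$gt)
  expect_true(base$traEdge >= 0 && base$traEdge <= 1)
  expect_true(base$traFull >= 0 && base$traFull <= 1)
  # add a spurious edge not present in gt
  ev <- lineageVertices(p$est)
  f1 <- ev[ev$frame == 1, ]
  f2 <- ev[ev$frame == 2, ]
  ee <- lineageEdges(p$est)
  added <- NULL
  for (i in seq_len(nrow(f1))) for (j in seq_len(nrow(f2))) {
    cand <- data.frame(fromFrame = 1L, fromId = f1$id[i], toFrame = 2L,
                       toId = f2$id[j], type = "track")
    key <- paste(cand$fromFrame, cand$fromId, cand$toFrame, cand$toId)
    eKey <- paste(ee$fromFrame, ee$fromId, ee$toFrame, ee$toId)
    gtE <- lineageEdges(p$gt)
    gKey <- paste(gtE$fromFrame, gtE$fromId, gtE$toFrame, gtE$toId)
    okIncoming <- !any(ee$toFrame == 2 & ee$toId == f2$id[j])
    okOutgoing <- !any(ee$fromFrame == 1 & ee$fromId == f1$id[i] &
                       ee$type == "track")
    if (!(key %in% eKey) && !(key %in% gKey) && okIncoming && okOutgoing) {
      added <- cand
      break
    }
  }
  if (!is.null(added)) {
    worse <- makeGraph(ev, rbind(ee, added))
    tr2 <- traScores(worse, p$gt)
    expect_lte(tr2$traEdge, base$traEdge)
    expect_lte(tr2$traFull, base$traFull)
  } else {
    succeed("no legal spurious edge existed for this fixture")
  }
})
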