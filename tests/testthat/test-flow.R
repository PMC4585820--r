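test_that("reweighted outflow plus negative teleport is conserved", {
  set.seed(11)
  for (rep in 1:30) {
    g <- randomSignedGraph(sample(6:20, 1))
    p <- randomPartitionOf(g, sample(2:4, 1))
    fm <- reweightFlows(g, p)
    expect_lt(max(abs(Matrix::rowSums(fm@trans) + fm@teleport - 1)), 1e-12)
    expect_true(all(fm@trans@x >= 0))
    expect_true(all(fm@teleport >= -1e-15 & fm@teleport <= 1 + 1e-15))
  }
})

test_that("without negative ties the flows are the unchanged w+/s+", {
  set.seed(12)
  for (rep in 1:10) {
    g <- randomSignedGraph(10, ppos = 0.3, pneg = 0)
    p <- randomPartitionOf(g, 3)
    fm <- reweightFlows(g, p)
    expect_equal(unname(fm@teleport), rep(0, 10))
    sp <- unname(posStrength(g))
    pe <- posEdges(g)
    for (r in seq_len(nrow(pe))) {
      i <- pe[r, 1]; j <- pe[r, 2]
      expect_equal(fm@trans[i, j], as.numeric(pe[r, 3]) / sp[i])
      expect_equal(fm@trans[j, i], as.numeric(pe[r, 3]) / sp[j])
    }
  }
})

test_that("worked neighborhood: cancelled module flow returns inside, internal negative teleports 3/8", {
  fx <- reweightFixture()
  fm <- reweightFlows(fx$graph, fx$partition)
  # equal +/- weight toward module 2: no flow to any of its nodes
  expect_equal(fm@trans[1, 4], 0)
  expect_equal(fm@trans[1, 5], 0)
  expect_equal(fm@backflow[1], 1 / 4)
  # flow toward module 3 untouched
  expect_equal(fm@trans[1, 6], 1 / 4)
  # internal mass (1/2 base + 1/4 backflow) halved by the internal negative
  expect_equal(fm@teleport[1], 3 / 8)
  expect_equal(fm@trans[1, 2], 3 / 16)
  expect_equal(fm@trans[1, 3], 3 / 16)
})

test_that("internal negatives at least as heavy as internal positives remove all internal flow", {
  # node 1: one internal positive (to 2), internal negative of weight 2 (to
  # 3), one external positive; internal mass must teleport entirely
  g <- SignedGraph(posEdges = rbind(c(1, 2, 1), c(1, 4, 1), c(2, 3, 1),
                                    c(3, 4, 1)),
                   negEdges = rbind(c(1, 3, 2)))
  p <- Partition(c(1, 1, 1, 2))
  fm <- reweightFlows(g, p)
  expect_equal(fm@trans[1, 2], 0)
  expect_equal(fm@teleport[1], 1 / 2)  # full internal mass, no backflow
  # a node with zero positive strength is rejected with guidance
  g0 <- SignedGraph(posEdges = cbind(1, 2, 1), negEdges = cbind(2, 3, 1))
  expect_error(reweightFlows(g0, allInOnePartition(g0)), "preprocess")
})

test_that("stationary distribution matches closed forms and reports non-convergence", {
  ring <- ringGraph(4)
  vd <- stationaryDistribution(reweightFlows(ring, allInOnePartition(ring)))
  expect_equal(vd@pVisit, rep(1 / 4, 4), tolerance = 1e-12)
  set.seed(13)
  g <- randomSignedGraph(15, ppos = 0.3, pneg = 0)
  sp <- unname(posStrength(g))
  vd2 <- stationaryDistribution(reweightFlows(g, randomPartitionOf(g, 3)))
  expect_equal(vd2@pVisit, sp / sum(sp), tolerance = 1e-10)
  expect_error(
    stationaryDistribution(reweightFlows(g, allInOnePartition(g)),
                           maxIter = 2L),
    "converge")
})

test_that("all-in-one partitions have zero exits and pure node entropy", {
  ring <- ringGraph(4)
  expect_equal(simap(ring, allInOnePartition(ring)), 2)
  set.seed(14)
  g <- randomSignedGraph(12, ppos = 0.3, pneg = 0)
  fm <- reweightFlows(g, allInOnePartition(g))
  vd <- stationaryDistribution(fm)
  expect_equal(vd@qExit, 0)
  expect_equal(simap(g, allInOnePartition(g)),
               -sum(ifelse(vd@pVisit > 0,
                           vd@pVisit * log2(vd@pVisit), 0)))
})

test_that("on unsigned graphs simap equals the brute-force two-level map equation", {
  set.seed(15)
  for (rep in 1:20) {
    g <- randomSignedGraph(sample(5:15, 1), ppos = 0.35, pneg = 0)
    p <- randomPartitionOf(g, sample(2:4, 1))
    m <- membership(p)[nodeNames(g)]
    expect_equal(simap(g, p), oracleMapEquation(g, unname(m)),
                 tolerance = 1e-10)
  }
})

test_that("negative ties between modules without positive inter-ties add no information", {
  cl <- rbind(t(combn(1:4, 2)), t(combn(5:8, 2)))
  base <- SignedGraph(posEdges = cbind(cl, 1))
  p <- Partition(rep(1:2, each = 4))
  withNeg <- SignedGraph(posEdges = cbind(cl, 1),
                         negEdges = rbind(c(1, 5, 1), c(2, 6, 1), c(3, 7, 1)))
  expect_equal(simap(withNeg, p), simap(base, p), tolerance = 1e-12)
})
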