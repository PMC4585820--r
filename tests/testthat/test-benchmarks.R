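test_that("zero mixing yields disjoint communities matching the ground truth", {
  lfr <- generateLFR(nNodes = 300, muOut = 0, meanDegree = 10,
                     maxDegree = 25, minCommunity = 26, maxCommunity = 60,
                     seed = 41)
  m <- membership(lfr$truth)[nodeNames(lfr$graph)]
  pe <- posEdges(lfr$graph)
  expect_true(all(m[pe[, 1]] == m[pe[, 2]]))
  expect_equal(omegaNeg(lfr$graph), 0)
})

test_that("realized mixing and degrees track the nominal parameters", {
  lfr <- generateLFR(nNodes = 1000, muOut = 0.3, seed = 42)
  expect_lt(abs(lfr$empirical$muOut - 0.3), 0.05)
  expect_lt(abs(lfr$empirical$meanDegree - 20), 3)
  k <- unname(posStrength(lfr$graph))
  expect_lte(max(k), 50)
  expect_equal(sort(unique(membership(lfr$truth))),
               seq_len(nModules(lfr$truth)))
  sz <- moduleSizes(lfr$truth)
  expect_true(all(sz >= 19 & sz <= 101))  # +/-1 from size fitting
  # graphs are simple: no duplicate edges, no self-loops (class validity
  # enforces this, but assert the generator obeyed it after repair)
  pe <- posEdges(lfr$graph)
  expect_true(all(pe[, 1] < pe[, 2]))
  expect_false(anyDuplicated(paste(pe[, 1], pe[, 2])) > 0)
})

test_that("generation is deterministic in the seed", {
  a <- smallLFR(200, 0.2, seed = 43)
  b <- smallLFR(200, 0.2, seed = 43)
  d <- smallLFR(200, 0.2, seed = 44)
  expect_identical(posEdges(a$graph), posEdges(b$graph))
  expect_identical(membership(a$truth), membership(b$truth))
  expect_false(identical(posEdges(a$graph), posEdges(d$graph)))
  cpA <- smallCoupled(120, muC = 0.2, muNegC = 0.2, seed = 45)
  cpB <- smallCoupled(120, muC = 0.2, muNegC = 0.2, seed = 45)
  expect_identical(posEdges(cpA$graph), posEdges(cpB$graph))
  expect_identical(negEdges(cpA$graph), negEdges(cpB$graph))
})

test_that("sign flipping hits the worked per-node class fractions", {
  lfr <- generateLFR(nNodes = 1000, muOut = 0.6, seed = 46)
  sg <- signifyLFR(lfr$graph, lfr$truth, muNegOut = 0.25, seed = 47)
  g <- sg$graph
  m <- membership(lfr$truth)[nodeNames(g)]
  k <- unname(posStrength(g) + negStrength(g))
  pe <- posEdges(g); ne <- negEdges(g)
  cnt <- function(e, same) {
    keep <- (m[e[, 1]] == m[e[, 2]]) == same
    v <- numeric(1000)
    t1 <- rowsum(rep(1, 2 * sum(keep)), c(e[keep, 1], e[keep, 2]))
    v[as.integer(rownames(t1))] <- t1[, 1]
    v
  }
  intPos <- mean(cnt(pe, TRUE) / k)
  extPos <- mean(cnt(pe, FALSE) / k)
  extNeg <- mean(cnt(ne, FALSE) / k)
  expect_lt(abs(intPos - 0.40), 0.05)
  expect_lt(abs(extNeg - 0.25), 0.05)
  expect_lt(abs(extPos - 0.35), 0.05)
  # identity when nothing is flipped
  sg0 <- signifyLFR(lfr$graph, lfr$truth, 0, 0, seed = 48)
  expect_identical(posEdges(sg0$graph), posEdges(lfr$graph))
  # infeasible request
  expect_error(signifyLFR(lfr$graph, lfr$truth, muNegOut = 0.9, seed = 49),
               "exceeds")
})

test_that("fully negative external ties can only improve the planted map", {
  lfr <- generateLFR(nNodes = 500, muOut = 0.4, seed = 50)
  sg <- signifyLFR(lfr$graph, lfr$truth, muNegOut = 0.4, seed = 51)
  mdlSigned <- simap(sg$graph, lfr$truth)
  mdlPositiveOnly <- simap(positiveSubgraph(sg$graph), lfr$truth)
  expect_lte(mdlSigned, mdlPositiveOnly + 1e-9)
})

test_that("coupling edges run only between twin communities and references nest", {
  cp <- smallCoupled(200, muC = 0.25, muNegC = 0.2, seed = 52)
  g <- cp$graph
  n <- numNodes(g) / 2
  mSingle <- membership(cp$partitions$single)[nodeNames(g)]
  mCouple <- membership(cp$partitions$couple)[nodeNames(g)]
  crossLayer <- function(e) (e[, 1] <= n) != (e[, 2] <= n)
  pe <- posEdges(g); ne <- negEdges(g)
  # every cross-layer edge joins twin communities (same coupled module)
  for (e in list(pe[crossLayer(pe), , drop = FALSE],
                 ne[crossLayer(ne), , drop = FALSE]))
    expect_true(all(mCouple[e[, 1]] == mCouple[e[, 2]]))
  # all negative edges are coupling edges
  expect_true(all(crossLayer(ne)))
  # single refines couple: each coupled module is exactly two single modules
  expect_true(all(vapply(split(mSingle, mCouple),
                         function(x) length(unique(x)), 0L) == 2))
  expect_equal(nModules(cp$partitions$allInOne), 1)
  # zero coupling: two disconnected identical layers
  cp0 <- smallCoupled(150, seed = 53)
  pe0 <- posEdges(cp0$graph)
  expect_false(any((pe0[, 1] <= 150) != (pe0[, 2] <= 150)))
  expect_equal(nrow(negEdges(cp0$graph)), 0)
})

test_that("negatives-only coupling keeps the separated structure as the best map", {
  for (mnc in c(0.2, 0.5)) {
    cp <- smallCoupled(200, muC = 0, muNegC = mnc,
                       seed = 54 + round(10 * mnc))
    expect_lt(simap(cp$graph, cp$partitions$single),
              simap(cp$graph, cp$partitions$couple))
  }
})
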