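test_that("edge lists parse sign tokens, merge orientations and count totals", {
  f <- withr::local_tempfile()
  writeLines(c("# comment", "1 2 +1", "2 3 -1"), f)
  g <- readEdgeList(f)
  expect_equal(numNodes(g), 3)
  expect_equal(omegaPos(g), 2)
  expect_equal(omegaNeg(g), 2)

  writeLines(character(0), f)
  g0 <- readEdgeList(f)
  expect_equal(numNodes(g0), 0)
  expect_equal(nrow(posEdges(g0)) + nrow(negEdges(g0)), 0)

  # reciprocal consistent pair collapses to one undirected +1 edge
  writeLines(c("1 2 1", "2 1 1"), f)
  res <- preprocessSignedGraph(readEdgeList(f, directed = TRUE))
  expect_equal(nrow(posEdges(res$graph)), 1)
  expect_equal(unname(posEdges(res$graph)[1, "weight"]), 1)

  writeLines(c("1 2 1", "2 3"), f)
  expect_error(readEdgeList(f), "line 2")
  writeLines(c("1 2 0"), f)
  expect_error(readEdgeList(f), "zero weight")
  writeLines(c("1 1 1", "1 2 1"), f)
  expect_warning(g1 <- readEdgeList(f), "self-loop")
  expect_equal(nrow(posEdges(g1)), 1)
  # bare +/- tokens
  writeLines(c("a b +", "b c -"), f)
  g2 <- readEdgeList(f)
  expect_equal(unname(posStrength(g2)[c("a", "b")]), c(1, 1))
  expect_equal(unname(negStrength(g2)["c"]), 1)
})

test_that("preprocessing applies the three cleaning rules in order", {
  # both members of an inconsistent reciprocal pair are dropped entirely
  de <- data.frame(from = c("u", "v", "x", "y"), to = c("v", "u", "y", "x"),
                   weight = c(1, -1, 1, 1))
  class(de) <- c("directedEdgeSet", "data.frame")
  res <- preprocessSignedGraph(de)
  expect_equal(res$report$inconsistentFraction, 0.5)
  expect_equal(sort(nodeNames(res$graph)), c("x", "y"))

  # hand trace: consistent pair {u,v}; component {x,y,z} wins; x loses its
  # only (negative) edge class -> removed with the re-taken component
  de2 <- data.frame(from = c("u", "v", "x", "y"),
                    to = c("v", "u", "y", "z"),
                    weight = c(1, 1, -1, 1))
  class(de2) <- c("directedEdgeSet", "data.frame")
  res2 <- preprocessSignedGraph(de2)
  expect_equal(sort(nodeNames(res2$graph)), c("y", "z"))
  expect_equal(res2$report$zeroPositiveRemoved, 1)

  # already-clean graph is a fixed point
  g <- cliquePair(3)
  res3 <- preprocessSignedGraph(g)
  expect_equal(res3$report$zeroPositiveRemoved, 0)
  expect_equal(numNodes(res3$graph), numNodes(g))
  expect_equal(posEdges(res3$graph), posEdges(g))
})

test_that("preprocessing is idempotent and directed totals double edge sums", {
  set.seed(71)
  for (rep in 1:10) {
    g <- randomSignedGraph(sample(6:15, 1))
    expect_equal(omegaPos(g), 2 * sum(posEdges(g)[, 3]))
    expect_equal(omegaNeg(g), 2 * sum(negEdges(g)[, 3]))
    once <- preprocessSignedGraph(g)$graph
    twice <- preprocessSignedGraph(once)$graph
    expect_equal(posEdges(twice), posEdges(once))
    expect_equal(negEdges(twice), negEdges(once))
    expect_equal(nodeNames(twice), nodeNames(once))
  }
})

test_that("positive subgraph drops negatives and keeps nodes and weights", {
  g <- cliquePair(3, bridges = 2, bridgeSign = -1)
  gp <- positiveSubgraph(g)
  expect_equal(omegaNeg(gp), 0)
  expect_equal(omegaPos(gp), omegaPos(g))
  expect_equal(numNodes(gp), numNodes(g))
  # two nodes joined only by a negative edge become isolated
  g2 <- SignedGraph(negEdges = cbind(1, 2, 1), nodes = c("a", "b"))
  expect_equal(unname(posStrength(positiveSubgraph(g2))), c(0, 0))
  # no negative edges: identity
  g3 <- ringGraph(5)
  expect_equal(posEdges(positiveSubgraph(g3)), posEdges(g3))
})

test_that("partition files round-trip and validate their node set", {
  p <- Partition(c(a = 1, b = 1, c = 2, d = 3, e = 2))
  f <- withr::local_tempfile()
  writePartition(p, f)
  expect_equal(nvi(readPartition(f), p), 0)
  expect_equal(length(readLines(f)), 5)
  g <- SignedGraph(posEdges = cbind(1, 2, 1), nodes = c("a", "zz"))
  expect_error(readPartition(f, graph = g), "missing node|unknown node")
  writePartition(allInOnePartition(letters[1:5]), f)
  expect_equal(nModules(readPartition(f)), 1)
})

test_that("module summaries match a brute-force recount", {
  set.seed(5)
  for (rep in 1:5) {
    g <- randomSignedGraph(10)
    p <- randomPartitionOf(g, 3)
    s <- moduleSummaries(g, p)
    m <- membership(p)[nodeNames(g)]
    Ap <- denseAdj(posEdges(g), 10)
    for (c in seq_len(nModules(p))) {
      expect_equal(s$n[c], sum(m == c))
      expect_equal(s$wPosIn[c], sum(Ap[m == c, m == c]))
      expect_equal(s$wPosOut[c], sum(Ap[m == c, m != c]))
    }
    expect_equal(sum(s$wPosIn + s$wPosOut), omegaPos(g))
    expect_equal(sum(s$wNegIn + s$wNegOut), omegaNeg(g))
  }
})
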