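test_that("CPM value matches hand arithmetic and the pairwise oracle", {
  g <- cliquePair(3, bridges = 0)
  cliques <- Partition(rep(1:2, each = 3))
  expect_equal(cpmValue(g, cliques, lambda = 0.5, alpha = 1), 6)
  expect_equal(cpmValue(g, allInOnePartition(g), lambda = 0.5, alpha = 1), -3)
  set.seed(21)
  for (rep in 1:20) {
    gr <- randomSignedGraph(sample(5:12, 1))
    p <- randomPartitionOf(gr, 3)
    m <- unname(membership(p)[nodeNames(gr)])
    lam <- runif(1); lamN <- runif(1, 0, 0.3); alp <- runif(1)
    expect_equal(cpmValue(gr, p, lam, lamN, alp),
                 oracleCPM(gr, m, lam, lamN, alp), tolerance = 1e-10)
  }
})

test_that("signed CPM at alpha 0.5 is half the unsigned CPM of the net-weight graph", {
  set.seed(22)
  for (rep in 1:100) {
    g <- randomSignedGraph(sample(5:15, 1))
    p <- randomPartitionOf(g, sample(2:4, 1))
    m <- unname(membership(p)[nodeNames(g)])
    lam <- runif(1)
    s <- moduleSummaries(g, p)
    netUnsigned <- sum((s$wPosIn - s$wNegIn) - lam * s$n * (s$n - 1))
    expect_equal(cpmValue(g, p, lam, lambdaNeg = 0, alpha = 0.5),
                 0.5 * netUnsigned, tolerance = 1e-10)
  }
})

test_that("signed modularity reduces to Newman modularity and matches igraph on positive graphs", {
  g <- cliquePair(3)
  p <- Partition(rep(1:2, each = 3))
  ig <- igraph::graph_from_edgelist(posEdges(g)[, 1:2], directed = FALSE)
  expect_equal(signedModularity(g, p),
               igraph::modularity(ig, membership = rep(1:2, each = 3)))
  # singleton closed form: Q = -sum (s_i / omega)^2
  sing <- singletonPartition(g)
  sp <- unname(posStrength(g))
  expect_equal(signedModularity(g, sing), -sum((sp / omegaPos(g))^2))
  # signed case against the pairwise oracle
  set.seed(23)
  for (rep in 1:20) {
    gr <- randomSignedGraph(sample(6:12, 1))
    pr <- randomPartitionOf(gr, 3)
    m <- unname(membership(pr)[nodeNames(gr)])
    expect_equal(signedModularity(gr, pr), oracleSignedModularity(gr, m),
                 tolerance = 1e-10)
  }
})

test_that("local move deltas equal from-scratch recomputation (fuzz)", {
  set.seed(24)
  for (rep in 1:200) {
    g <- randomSignedGraph(sample(5:14, 1))
    n <- numNodes(g)
    p <- randomPartitionOf(g, sample(2:4, 1))
    m <- unname(membership(p)[nodeNames(g)])
    grp <- which(m == m[sample(n, 1)])
    kappa <- sample(grp, sample(length(grp), 1))
    target <- sample(0:max(m), 1)
    if (target != 0 && target == m[kappa[1]]) target <- 0
    m2 <- m; m2[kappa] <- if (target == 0) max(m) + 1L else target
    lam <- runif(1); alp <- runif(1)
    expect_equal(
      deltaMove(g, p, kappa, target, "signed_cpm", lambda = lam, alpha = alp),
      oracleCPM(g, m2, lam, 0, alp) - oracleCPM(g, m, lam, 0, alp),
      tolerance = 1e-10)
    expect_equal(
      deltaMove(g, p, kappa, target, "signed_modularity"),
      oracleSignedModularity(g, m2) - oracleSignedModularity(g, m),
      tolerance = 1e-10)
  }
})

test_that("degenerate deltas: isolated nodes and internal-negative escapes", {
  # isolated node: only the lambda pair-count terms remain
  g <- SignedGraph(posEdges = rbind(c(1, 2, 1), c(2, 3, 1), c(4, 5, 1)),
                   nodes = as.character(1:6))
  p <- Partition(c(1, 1, 1, 2, 2, 2))
  lam <- 0.3
  expect_equal(deltaMove(g, p, 6, 1, "signed_cpm", lambda = lam, alpha = 1),
               -lam * 2 * (3 - 3 + 1) * 1 + lam * 0)  # leaves 2 others, joins 3
  # moving out a node whose only ties are internal negatives improves CPM
  g2 <- SignedGraph(posEdges = rbind(c(2, 3, 1), c(3, 4, 1), c(1, 4, 1)),
                    negEdges = rbind(c(1, 2, 1), c(1, 3, 1)))
  p2 <- Partition(c(1, 1, 1, 2))
  expect_gt(deltaMove(g2, p2, 1, 0, "signed_cpm", lambda = 0), 0)
  expect_error(deltaMove(g2, p2, c(1, 4), 0, "signed_cpm"), "multiple modules")
})

test_that("Louvain attains the enumerated optimum on small fixtures", {
  # two 3-cliques, one positive bridge, lambda 0.5: cliques win over all
  # 203 partitions of 6 nodes
  g <- cliquePair(3, bridges = 1)
  m6 <- unname(membership(louvainSigned(g, "signed_cpm", lambda = 0.5,
                                        seed = 1))[nodeNames(g)])
  best <- max(vapply(enumeratePartitions(6), function(m)
    oracleCPM(g, m, 0.5, 0, 0.5), 0))
  expect_equal(oracleCPM(g, m6, 0.5, 0, 0.5), best)
  expect_equal(sort(tabulate(m6)), c(3, 3))

  # negative bridges keep the cliques apart at low lambda
  gn <- cliquePair(3, bridges = 3, bridgeSign = -1)
  mn <- unname(membership(louvainSigned(gn, "signed_cpm", lambda = 0.1,
                                        seed = 1))[nodeNames(gn)])
  bestN <- max(vapply(enumeratePartitions(6), function(m)
    oracleCPM(gn, m, 0.1, 0, 0.5), 0))
  expect_equal(oracleCPM(gn, mn, 0.1, 0, 0.5), bestN)
  expect_equal(sort(tabulate(mn)), c(3, 3))

  # lambda above every weight: all singletons
  ms <- louvainSigned(cliquePair(3), "signed_cpm", lambda = 1.5, seed = 1)
  expect_equal(nModules(ms), 6)

  # lambda 0 on a connected positive graph: all-in-one
  m0 <- louvainSigned(cliquePair(3), "signed_cpm", lambda = 0, seed = 1)
  expect_equal(nModules(m0), 1)
})

test_that("unsigned map optimizer attains the enumerated minimum description length", {
  # ring of 4: no split beats the 2-bit single module (all 15 partitions)
  ring <- ringGraph(4)
  mems <- enumeratePartitions(4)
  mdls <- vapply(mems, function(m) oracleMapEquation(ring, m), 0)
  expect_equal(min(mdls), 2)
  pr <- optimizeUnsignedMap(ring, seed = 1)
  expect_equal(nModules(pr), 1)

  # two 4-cliques with a bridge: the cliques minimize over all 4140
  # partitions of 8 nodes
  g <- cliquePair(4, bridges = 1)
  mems8 <- enumeratePartitions(8)
  mdls8 <- vapply(mems8, function(m) oracleMapEquation(g, m), 0)
  pm <- optimizeUnsignedMap(g, seed = 1)
  m8 <- unname(membership(pm)[nodeNames(g)])
  expect_equal(oracleMapEquation(g, m8), min(mdls8), tolerance = 1e-12)
  expect_equal(sort(tabulate(m8)), c(4, 4))
})

test_that("refinement is non-decreasing and repairs adversarial starts", {
  g <- cliquePair(3, bridges = 1)
  set.seed(26)
  for (rep in 1:20) {
    p0 <- randomPartitionOf(g, 3)
    v0 <- cpmValue(g, p0, 0.5)
    p1 <- refinePartition(g, p0, "signed_cpm", lambda = 0.5, seed = rep)
    v1 <- cpmValue(g, p1, 0.5)
    expect_gte(v1, v0 - 1e-12)
    expect_equal(v1, 3)  # the enumerated optimum (alpha 0.5)
  }
  # an optimal partition is a fixed point
  opt <- Partition(rep(1:2, each = 3), nodeNames(g))
  pf <- refinePartition(g, opt, "signed_cpm", lambda = 0.5, seed = 1)
  expect_equal(nvi(pf, opt), 0)
})

test_that("optimized CPM quality is comparable to igraph's Leiden CPM on positive graphs", {
  lfr <- smallLFR(300, 0.2, seed = 27)
  g <- lfr$graph
  lam <- 0.1
  mine <- louvainSigned(g, "signed_cpm", lambda = lam, alpha = 1, seed = 1)
  ig <- igraph::graph_from_edgelist(posEdges(g)[, 1:2], directed = FALSE)
  lei <- igraph::cluster_leiden(ig, objective_function = "CPM",
                                resolution = lam, n_iterations = 5)
  # igraph counts each undirected edge and pair once: convert to directed
  leiVal <- 2 * lei$quality
  expect_gte(cpmValue(g, mine, lam, alpha = 1), 0.98 * leiVal)
})
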