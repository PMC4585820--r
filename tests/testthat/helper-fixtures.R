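# Graph fixtures built in code; all weights +/-1 unless stated.

ringGraph <- function(n = 4) {
  SignedGraph(posEdges = cbind(seq_len(n), c(seq_len(n)[-1], 1), 1))
}

# k-cliques joined by bridge edges (positive or negative)
cliquePair <- function(k = 3, bridges = 1, bridgeSign = +1) {
  cl <- rbind(t(combn(seq_len(k), 2)), t(combn(k + seq_len(k), 2)))
  br <- cbind(seq_len(bridges), k + seq_len(bridges))
  if (bridgeSign > 0)
    SignedGraph(posEdges = cbind(rbind(cl, br), 1))
  else
    SignedGraph(posEdges = cbind(cl, 1), negEdges = cbind(br, 1))
}

# random signed graph with a guaranteed positive spanning path (every node
# has positive strength, as after preprocessing)
randomSignedGraph <- function(n, ppos = 0.25, pneg = 0.1) {
  pairs <- t(combn(n, 2))
  r <- runif(nrow(pairs))
  pos <- pairs[r < ppos, , drop = FALSE]
  neg <- pairs[r >= ppos & r < ppos + pneg, , drop = FALSE]
  path <- cbind(seq_len(n - 1), 2:n)
  key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  pos <- rbind(pos, path[!(key(path) %in% key(pos)), , drop = FALSE])
  neg <- neg[!(key(neg) %in% key(pos)), , drop = FALSE]
  wp <- cbind(pos, round(runif(nrow(pos), 0.5, 2), 2))
  wn <- if (nrow(neg)) cbind(neg, round(runif(nrow(neg), 0.5, 2), 2)) else NULL
  SignedGraph(posEdges = wp, negEdges = wn)
}

# small-graph benchmark settings: degree and community-size bounds chosen
# so every internal degree fits in every community (always feasible)
smallLFR <- function(nNodes, muOut, seed, ...) {
  generateLFR(nNodes = nNodes, muOut = muOut, meanDegree = 10,
              maxDegree = 20, minCommunity = 21, maxCommunity = 50,
              seed = seed, ...)
}

smallCoupled <- function(nNodes, muOut = 0.3, muC = 0, muNegC = 0, seed) {
  generateCoupledLFR(nNodes = nNodes, muOut = muOut, muC = muC,
                     muNegC = muNegC, meanDegree = 10, maxDegree = 20,
                     minCommunity = 21, maxCommunity = 50, seed = seed)
}

randomPartitionOf <- function(g, K) {
  m <- sample(K, numNodes(g), replace = TRUE)
  Partition(m, nodeNames(g))
}

# The worked reweighting neighborhood: node 1 in module {1,2,3,7} with
# internal positives to 2 and 3, an internal negative to 7, equal positive
# and negative weight toward module {4,5}, and an untouched positive link
# to module {6}. Expected: flow toward {4,5} fully channeled back (backflow
# 1/4), then 3/8 of the total flow teleported due to the internal negative.
reweightFixture <- function() {
  g <- SignedGraph(
    posEdges = rbind(c(1, 2, 1), c(1, 3, 1), c(1, 4, 1), c(1, 6, 1),
                     c(2, 3, 1), c(4, 5, 1), c(5, 6, 1), c(2, 7, 1)),
    negEdges = rbind(c(1, 5, 1), c(1, 7, 1)))
  list(graph = g, partition = Partition(c(1, 1, 1, 2, 2, 3, 1)))
}
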