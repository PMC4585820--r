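# Independent brute-force evaluators used as oracles; deliberately coded
# from the textbook definitions (dense matrices, explicit entropy sums)
# rather than through the package's own computation paths.

denseAdj <- function(edges, n) {
  A <- matrix(0, n, n)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]; w <- edges[r, 3]
    A[i, j] <- A[i, j] + w
    A[j, i] <- A[j, i] + w
  }
  A
}

# Standard two-level map equation on an unsigned undirected graph:
# L = q H(Q) + sum_c p_c H(P_c), flows s_i / omega, exits boundary / omega.
oracleMapEquation <- function(g, memb) {
  n <- numNodes(g)
  A <- denseAdj(posEdges(g), n)
  om <- sum(A)
  p <- rowSums(A) / om
  ent <- function(x) { x <- x[x > 0]; -sum(x * log2(x)) }
  K <- max(memb)
  q <- vapply(seq_len(K), function(c)
    sum(A[memb == c, memb != c, drop = FALSE]) / om, 0)
  qt <- sum(q)
  L <- if (qt > 0) qt * ent(q / qt) else 0
  for (c in seq_len(K)) {
    pc <- q[c] + sum(p[memb == c])
    if (pc > 0) L <- L + pc * ent(c(q[c], p[memb == c]) / pc)
  }
  L
}

# Signed CPM from its pairwise definition (directed node pairs).
oracleCPM <- function(g, memb, lambda, lambdaNeg = 0, alpha = 0.5) {
  n <- numNodes(g)
  Ap <- denseAdj(posEdges(g), n)
  An <- denseAdj(negEdges(g), n)
  hp <- 0; hn <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || memb[i] != memb[j]) next
    hp <- hp + Ap[i, j] - lambda
    hn <- hn + An[i, j] - lambdaNeg
  }
  alpha * hp - (1 - alpha) * hn
}

# Signed modularity from the pairwise Newman definition per subgraph.
oracleSignedModularity <- function(g, memb, alpha = NULL) {
  n <- numNodes(g)
  newman <- function(A) {
    om <- sum(A)
    if (om == 0) return(0)
    s <- rowSums(A)
    tot <- 0
    for (i in seq_len(n)) for (j in seq_len(n))
      if (memb[i] == memb[j]) tot <- tot + A[i, j] / om - s[i] * s[j] / om^2
    tot
  }
  Ap <- denseAdj(posEdges(g), n); An <- denseAdj(negEdges(g), n)
  op <- sum(Ap); on_ <- sum(An)
  if (is.null(alpha)) alpha <- if (op + on_ > 0) op / (op + on_) else 1
  if (on_ == 0) return(newman(Ap))
  alpha * newman(Ap) - (1 - alpha) * newman(An)
}

# All set partitions of n items as restricted-growth membership vectors.
enumeratePartitions <- function(n) {
  out <- vector("list", 0)
  rec <- function(prefix, maxUsed) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (v in seq_len(maxUsed + 1L)) rec(c(prefix, v), max(maxUsed, v))
  }
  rec(integer(0), 0L)
  out
}
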