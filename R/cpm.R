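.objCode <- function(objective) {
  match(match.arg(objective,
                  c("signed_cpm", "signed_modularity", "unsigned_map")),
        c("signed_cpm", "signed_modularity", "unsigned_map")) - 1L
}

.edgeArgs <- function(g) {
  list(n = numNodes(g), pos = g@posEdges, neg = g@negEdges)
}

#' Signed Constant Potts Model value
#'
#' `H = alpha * sum_c (w+_c - lambda * N_c (N_c - 1))
#'    - (1 - alpha) * sum_c (w-_c - lambdaNeg * N_c (N_c - 1))`
#'
#' where `w+_c` / `w-_c` are the directed internal weight sums of module `c`
#' (each undirected internal edge counted twice) and `N_c (N_c - 1)` the
#' directed internal pair count. Higher is better (maximization
#' convention). The canonical signed CPM keeps `lambdaNeg = 0`, so any
#' density of internal negative ties is punished, and `alpha = 0.5`, under
#' which the signed value equals exactly half the unsigned CPM value of the
#' net-weight graph `w+ - w-` at the same resolution.
#'
#' @param g a [SignedGraph-class].
#' @param partition a [Partition-class].
#' @param lambda resolution of the positive subgraph (density threshold
#'   above which internal weight is rewarded).
#' @param lambdaNeg resolution applied to the negative subgraph; 0 in the
#'   canonical method.
#' @param alpha relative weight of the positive term, in `[0, 1]`.
#' @param selfPairs if `TRUE`, use `N_c^2` instead of `N_c (N_c - 1)` as the
#'   internal pair count (a convention used by part of the CPM literature).
#' @return The objective value (a single number).
#' @examples
#' cl <- rbind(t(combn(1:3, 2)), t(combn(4:6, 2)))
#' g <- SignedGraph(posEdges = cbind(cl, 1))
#' cpmValue(g, Partition(c(1, 1, 1, 2, 2, 2)), lambda = 0.5, alpha = 1)  # 6
#' @export
cpmValue <- function(g, partition, lambda, lambdaNeg = 0, alpha = 0.5,
                     selfPairs = FALSE) {
  stopifnot(lambda >= 0, alpha >= 0, alpha <= 1)
  s <- moduleSummaries(g, partition)
  pairs <- if (selfPairs) s$n^2 else s$n * (s$n - 1)
  alpha * sum(s$wPosIn - lambda * pairs) -
    (1 - alpha) * sum(s$wNegIn - lambdaNeg * pairs)
}

#' Signed modularity
#'
#' `Q = alpha * Q+(G+, C) - (1 - alpha) * Q-(G-, C)` where `Q+` and `Q-`
#' are the Newman modularities of the positive and negative subgraphs. The
#' default balance `alpha = omegaPos / (omegaPos + omegaNeg)` weighs each
#' subgraph by its share of the total weight. On an all-positive graph the
#' value reduces to the plain Newman modularity (the degenerate negative
#' term is dropped when `omegaNeg = 0`).
#'
#' @inheritParams cpmValue
#' @param alpha relative importance of the positive subgraph; `NULL` (the
#'   default) uses `omegaPos / (omegaPos + omegaNeg)`.
#' @return The modularity value.
#' @export
signedModularity <- function(g, partition, alpha = NULL) {
  op <- omegaPos(g); on_ <- omegaNeg(g)
  if (is.null(alpha)) alpha <- if (op + on_ > 0) op / (op + on_) else 1
  s <- moduleSummaries(g, partition)
  qp <- if (op > 0) sum(s$wPosIn / op - ((s$wPosIn + s$wPosOut) / op)^2) else 0
  if (on_ == 0) return(qp)
  qn <- sum(s$wNegIn / on_ - ((s$wNegIn + s$wNegOut) / on_)^2)
  alpha * qp - (1 - alpha) * qn
}

#' Exact objective change for moving a node set
#'
#' Computes `H(after) - H(before)` for moving the node set `nodes` from its
#' current module to `target`, from module aggregates in time proportional
#' to the links incident to the set. Positive and negative subgraph
#' contributions are handled separately (the negative resolution is 0 for
#' the canonical signed CPM).
#'
#' @inheritParams cpmValue
#' @param nodes node labels (or integer indices) forming the set to move;
#'   they must currently share one module.
#' @param target module id to move into, or `0` for a fresh module.
#' @param objective `"signed_cpm"`, `"signed_modularity"` or
#'   `"unsigned_map"` (the latter evaluated on the positive subgraph with
#'   closed-form unsigned flows).
#' @return The objective change (positive means the move improves the
#'   objective under the maximization convention; for `"unsigned_map"` a
#'   positive value means the description length decreases).
#' @export
deltaMove <- function(g, partition, nodes, target,
                      objective = c("signed_cpm", "signed_modularity",
                                    "unsigned_map"),
                      lambda = 0, lambdaNeg = 0, alpha = NULL) {
  obj <- .objCode(objective)
  m <- .alignedMembership(g, partition)
  idx <- if (is.character(nodes)) match(nodes, g@nodes) else as.integer(nodes)
  if (anyNA(idx) || any(idx < 1) || any(idx > numNodes(g)))
    stop("unknown node in 'nodes'")
  if (length(unique(m[idx])) != 1L)
    stop("'nodes' spans multiple modules")
  if (is.null(alpha))
    alpha <- if (obj == 1L) {
      op <- omegaPos(g); on_ <- omegaNeg(g)
      if (op + on_ > 0) op / (op + on_) else 1
    } else 0.5
  target <- as.integer(target)
  if (target != 0L && (target < 1L || target > max(m)))
    stop("unknown target module")
  if (target != 0L && all(m[idx] == target)) return(0)
  a <- .edgeArgs(g)
  cpp_set_move_delta(a$n, a$pos, a$neg, obj, lambda, lambdaNeg, alpha,
                     as.integer(m), idx, target)
}

#' Louvain optimization of signed partition objectives
#'
#' Multi-level Louvain: starting from singletons, each node is repeatedly
#' moved (in seeded random sweep order) to the neighboring module that
#' maximally improves the objective, modules are then folded into
#' super-nodes (positive and negative weights aggregated separately) and
#' the procedure recurses until no improvement remains. The result is then
#' refined (see [refinePartition()]) for `refineRounds` rounds.
#'
#' @inheritParams deltaMove
#' @param lambda,lambdaNeg,alpha objective parameters; `alpha = NULL` means
#'   0.5 for CPM and the weight-share default for modularity.
#' @param seed integer seed for the sweep order.
#' @param refineRounds refinement rounds after the Louvain phase
#'   (default 4; 0 disables refinement).
#' @param eps minimal improvement accepted for a move (guards against
#'   floating-point move cycles).
#' @return A [Partition-class].
#' @examples
#' cl <- rbind(t(combn(1:3, 2)), t(combn(4:6, 2)), c(3, 4))
#' g <- SignedGraph(posEdges = cbind(cl, 1))
#' louvainSigned(g, "signed_cpm", lambda = 0.5, seed = 1)  # the two cliques
#' @export
louvainSigned <- function(g, objective = c("signed_cpm", "signed_modularity",
                                           "unsigned_map"),
                          lambda = 0.05, lambdaNeg = 0, alpha = NULL,
                          seed = 1L, refineRounds = 4L, eps = 1e-12) {
  obj <- .objCode(objective)
  if (is.null(alpha))
    alpha <- if (obj == 1L) {
      op <- omegaPos(g); on_ <- omegaNeg(g)
      if (op + on_ > 0) op / (op + on_) else 1
    } else 0.5
  if (numNodes(g) == 0L) stop("empty graph")
  a <- .edgeArgs(g)
  if (obj == 2L) a$neg <- .emptyEdges()
  res <- cpp_optimize(a$n, a$pos, a$neg, obj, lambda, lambdaNeg, alpha,
                      as.integer(seed), as.integer(refineRounds), eps,
                      integer(0), TRUE)
  Partition(res$membership, g@nodes)
}

#' Refine a partition
#'
#' Alternates, for up to `rounds` rounds, (a) single-node move sweeps at
#' the leaf level and (b) re-running Louvain inside each module to find
#' submodules, which are then proposed as unit moves to neighboring modules
#' under exact global deltas. The objective never decreases; iteration
#' stops early at a fixed point.
#'
#' @inheritParams louvainSigned
#' @param partition the [Partition-class] to refine (typically a Louvain
#'   output, but any valid partition works).
#' @param rounds number of refinement rounds (default 4).
#' @return A [Partition-class] at least as good as the input.
#' @export
refinePartition <- function(g, partition,
                            objective = c("signed_cpm", "signed_modularity",
                                          "unsigned_map"),
                            lambda = 0.05, lambdaNeg = 0, alpha = NULL,
                            rounds = 4L, seed = 1L, eps = 1e-12) {
  obj <- .objCode(objective)
  if (is.null(alpha))
    alpha <- if (obj == 1L) {
      op <- omegaPos(g); on_ <- omegaNeg(g)
      if (op + on_ > 0) op / (op + on_) else 1
    } else 0.5
  m <- .alignedMembership(g, partition)
  a <- .edgeArgs(g)
  if (obj == 2L) a$neg <- .emptyEdges()
  res <- cpp_optimize(a$n, a$pos, a$neg, obj, lambda, lambdaNeg, alpha,
                      as.integer(seed), as.integer(rounds), eps,
                      as.integer(m), FALSE)
  Partition(res$membership, g@nodes)
}

#' Unsigned map-equation baseline
#'
#' Minimizes the standard (unsigned, two-level) map equation on the
#' positive subgraph with the shared Louvain-plus-refinement machinery,
#' ignoring negative ties. For undirected unsigned graphs the visit rates
#' are the closed-form `s_i / omega`, so local deltas are computed
#' incrementally from cached flows.
#'
#' @inheritParams louvainSigned
#' @return A [Partition-class] locally minimal for the unsigned map
#'   equation.
#' @export
optimizeUnsignedMap <- function(g, seed = 1L, refineRounds = 4L) {
  louvainSigned(positiveSubgraph(g), "unsigned_map", seed = seed,
                refineRounds = refineRounds)
}
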