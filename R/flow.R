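#' Reweight random-walk flows by negative ties
#'
#' Builds the partition-dependent flow model of the signed map equation.
#' For each node `i` in module `c`:
#'
#' 1. the positive flow toward every foreign module `c'` is scaled by
#'    `max(0, 1 - w-(i,c') / w+(i,c'))`, so it vanishes exactly when `i`'s
#'    negative weight toward `c'` matches or exceeds its positive weight;
#'    the removed mass (the *backflow* `p_back`) is redistributed over `i`'s
#'    internal positive links in proportion to their weights;
#' 2. the internal flow (original plus backflow) is then scaled by
#'    `max(0, 1 - w-(i,in) / w+(i,in))`; the mass removed here is the
#'    *negative teleport* of `i`, spread uniformly over all nodes of the
#'    network (including `i`) when walking.
#'
#' If `i` has no internal positive links the backflow has nowhere to land
#' and joins the negative teleport. On a graph without negative ties the
#' transition probabilities are the unchanged `w+(i,j)/s+(i)`. For every
#' node, reweighted outflow plus negative teleport sums to one.
#'
#' @param g a [SignedGraph-class]; every node must have positive strength
#'   (guaranteed after [preprocessSignedGraph()]).
#' @param partition a [Partition-class] over the nodes of `g`.
#' @return A [FlowModel-class].
#' @export
reweightFlows <- function(g, partition) {
  m <- .alignedMembership(g, partition)
  n <- numNodes(g)
  sp <- unname(posStrength(g))
  if (any(sp == 0))
    stop("node(s) with zero positive strength; run preprocessSignedGraph() first")
  K <- max(m)
  pe <- g@posEdges; ne <- g@negEdges
  if (!nrow(pe)) stop("graph has no positive edges")

  pi_ <- c(pe[, 1], pe[, 2]); pj <- c(pe[, 2], pe[, 1])
  pw <- c(pe[, 3], pe[, 3])
  pkey <- (pi_ - 1) * K + m[pj]
  t <- rowsum(pw, pkey)
  wPosIM <- t[match(pkey, as.numeric(rownames(t))), 1]

  wNegIM <- numeric(length(pkey))
  wNegIn <- numeric(n)
  if (nrow(ne)) {
    ni <- c(ne[, 1], ne[, 2]); nj <- c(ne[, 2], ne[, 1])
    nw <- c(ne[, 3], ne[, 3])
    nkey <- (ni - 1) * K + m[nj]
    tn <- rowsum(nw, nkey)
    hit <- match(pkey, as.numeric(rownames(tn)))
    wNegIM[!is.na(hit)] <- tn[hit[!is.na(hit)], 1]
    internalN <- m[ni] == m[nj]
    if (any(internalN)) {
      tt <- rowsum(nw[internalN], ni[internalN])
      wNegIn[as.integer(rownames(tt))] <- tt[, 1]
    }
  }

  internal <- m[pi_] == m[pj]
  wPosIn <- numeric(n)
  if (any(internal)) {
    tt <- rowsum(pw[internal], pi_[internal])
    wPosIn[as.integer(rownames(tt))] <- tt[, 1]
  }

  f <- pmax(0, 1 - wNegIM / wPosIM)           # per directed edge, by module
  back <- numeric(n)
  if (any(!internal)) {
    tt <- rowsum((pw[!internal] / sp[pi_[!internal]]) * (1 - f[!internal]),
                 pi_[!internal])
    back[as.integer(rownames(tt))] <- tt[, 1]
  }
  hasInt <- wPosIn > 0
  intMass <- ifelse(hasInt, wPosIn / sp + back, 0)
  gIn <- ifelse(hasInt, pmax(0, 1 - wNegIn / wPosIn), 0)
  teleport <- ifelse(hasInt, intMass * (1 - gIn), back)

  pprime <- numeric(length(pw))
  pprime[internal] <- (pw[internal] / wPosIn[pi_[internal]]) *
    intMass[pi_[internal]] * gIn[pi_[internal]]
  pprime[!internal] <- (pw[!internal] / sp[pi_[!internal]]) * f[!internal]
  keep <- pprime > 0
  trans <- Matrix::sparseMatrix(i = pi_[keep], j = pj[keep], x = pprime[keep],
                                dims = c(n, n))
  new("FlowModel", trans = as(trans, "dgCMatrix"), teleport = teleport,
      backflow = back, membership = as.integer(m), posStrength = sp,
      nodes = g@nodes)
}

setMethod("show", "FlowModel", function(object) {
  cat(sprintf(
    "FlowModel: %d nodes, %d reweighted links, total negative teleport %.4f\n",
    length(object@teleport), length(object@trans@x), sum(object@teleport)))
  invisible(object)
})

#' Stationary visit distribution with smart teleportation
#'
#' Power iteration of the teleport-augmented walk: from node `i`, with
#' probability `tau` the walker teleports to node `j` with probability
#' proportional to the positive strength of `j`; otherwise it follows the
#' reweighted transition probabilities, with the negative-teleport mass of
#' `i` spread uniformly over all nodes. Iteration starts from the uniform
#' distribution and stops when the L1 change between successive iterates
#' falls below `tol`. Following the smart-teleportation recipe, one extra
#' teleport-free step is then taken and those visit rates are returned;
#' module exit probabilities are likewise computed teleport-free.
#'
#' @param fm a [FlowModel-class].
#' @param tau teleportation rate (default 0.15).
#' @param tol L1 convergence threshold.
#' @param maxIter iteration cap; exceeding it is an error reporting the
#'   final residual.
#' @return A [VisitDistribution-class].
#' @export
stationaryDistribution <- function(fm, tau = 0.15, tol = 1e-14,
                                   maxIter = 10000L) {
  n <- length(fm@teleport)
  tw <- fm@posStrength / sum(fm@posStrength)
  tM <- Matrix::t(fm@trans)
  tele <- fm@teleport
  p <- rep(1 / n, n)
  res <- Inf
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    pn <- as.numeric(tM %*% p) + sum(p * tele) / n
    pn <- tau * tw + (1 - tau) * pn
    res <- sum(abs(pn - p))
    p <- pn
    if (res < tol) break
  }
  if (res >= tol)
    stop(sprintf("power iteration did not converge (L1 residual %.3e after %d iterations)",
                 res, it))
  p <- as.numeric(tM %*% p) + sum(p * tele) / n  # one teleport-free step

  m <- fm@membership
  K <- max(m)
  tt <- as(fm@trans, "TsparseMatrix")
  ei <- tt@i + 1L; ej <- tt@j + 1L
  intMass <- numeric(n)
  same <- m[ei] == m[ej]
  if (any(same)) {
    agg <- rowsum(tt@x[same], ei[same])
    intMass[as.integer(rownames(agg))] <- agg[, 1]
  }
  extMass <- pmax(0, 1 - tele - intMass)
  Nc <- tabulate(m, K)
  q <- numeric(K)
  agg <- rowsum(p * (extMass + tele * (n - Nc[m]) / n), m)
  q[as.integer(rownames(agg))] <- agg[, 1]
  new("VisitDistribution", pVisit = p, qExit = q, tau = tau,
      teleportWeights = tw, iterations = it, residual = res)
}

setMethod("show", "VisitDistribution", function(object) {
  cat(sprintf(
    "VisitDistribution: %d nodes, %d modules, converged in %d iterations (residual %.2e)\n",
    length(object@pVisit), length(object@qExit), object@iterations,
    object@residual))
  invisible(object)
})

.plogp <- function(x) {
  y <- numeric(length(x))
  pos <- x > 0
  y[pos] <- x[pos] * log2(x[pos])
  y
}

# Two-level description length (bits) from visit rates p, module exits q and
# a membership vector.
.twoLevelMDL <- function(p, q, m) {
  K <- max(m)
  Pc <- numeric(K)
  agg <- rowsum(p, m)
  Pc[as.integer(rownames(agg))] <- agg[, 1]
  sum(.plogp(sum(q))) - 2 * sum(.plogp(q)) + sum(.plogp(q + Pc)) -
    sum(.plogp(p))
}

#' Signed map equation (SiMap)
#'
#' Two-level description length, in bits, of a random walk on the signed
#' graph under the given partition: the expected code length per step when
#' module entries/exits use a first-level codebook and node visits a
#' per-module codebook, with walk flows reweighted by the negative ties
#' (see [reweightFlows()]). Lower is better. On a graph without negative
#' ties this is the standard unsigned two-level map equation.
#'
#' @inheritParams reweightFlows
#' @inheritParams stationaryDistribution
#' @return Description length in bits (a single number).
#' @examples
#' ring <- SignedGraph(posEdges = cbind(1:4, c(2, 3, 4, 1), 1))
#' simap(ring, allInOnePartition(ring))  # 2 bits: four equiprobable nodes
#' @export
simap <- function(g, partition, tau = 0.15, tol = 1e-14, maxIter = 10000L) {
  fm <- reweightFlows(g, partition)
  vd <- stationaryDistribution(fm, tau = tau, tol = tol, maxIter = maxIter)
  .twoLevelMDL(vd@pVisit, vd@qExit, fm@membership)
}
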