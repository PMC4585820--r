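# LFR-style benchmark generators: scale-free degrees and community sizes,
# configuration-model wiring with repair, per-node mixing control, and the
# signed / coupled extensions with their reference partitions.

.samplePowerlawInt <- function(nsamp, expo, lo, hi) {
  k <- lo:hi
  if (length(k) == 1) return(rep(k, nsamp))
  sample(k, nsamp, replace = TRUE, prob = k^(-expo))
}

# smallest-degree bound whose truncated power-law mean is closest to target
.solveDegreeMin <- function(expo, hi, target) {
  cand <- seq_len(hi - 1)
  means <- vapply(cand, function(lo) {
    k <- lo:hi
    sum(k^(1 - expo)) / sum(k^(-expo))
  }, 0)
  cand[which.min(abs(means - target))]
}

.sampleCommunitySizes <- function(n, expo, lo, hi) {
  if (n < 2 * lo)
    stop(sprintf("infeasible: %d nodes cannot host two communities of size >= %d",
                 n, lo))
  sizes <- integer(0)
  while (sum(sizes) < n)
    sizes <- c(sizes, .samplePowerlawInt(1, expo, lo, hi))
  guard <- 0
  while (sum(sizes) != n) {
    guard <- guard + 1
    if (guard > 10 * n) stop("could not fit community sizes to node count")
    if (sum(sizes) > n) {
      i <- which(sizes > lo)
      if (!length(i)) { sizes <- sizes[-length(sizes)]; next }
      i <- i[which.max(sizes[i])]
      sizes[i] <- sizes[i] - 1L
    } else {
      i <- which(sizes < hi)
      if (!length(i)) stop("could not fit community sizes to node count")
      i <- sample(i, 1)
      sizes[i] <- sizes[i] + 1L
    }
  }
  sizes
}

# LFR node-to-community assignment with kick-out replacement: every node
# needs a community that can host its internal degree.
.assignCommunities <- function(dInt, sizes) {
  n <- length(dInt); K <- length(sizes)
  comm <- rep(NA_integer_, n)
  count <- integer(K)
  pending <- sample.int(n)
  guard <- 0
  while (length(pending)) {
    guard <- guard + 1
    if (guard > 200 * n)
      stop("community assignment did not converge; spec likely infeasible")
    v <- pending[1]; pending <- pending[-1]
    feas <- which(sizes - 1 >= dInt[v])
    if (!length(feas))
      stop(sprintf("infeasible: internal degree %d exceeds every community size - 1",
                   dInt[v]))
    c <- if (length(feas) == 1) feas else sample(feas, 1)
    if (count[c] < sizes[c]) {
      comm[v] <- c; count[c] <- count[c] + 1L
    } else {
      members <- which(comm == c)
      u <- members[sample.int(length(members), 1)]
      comm[u] <- NA_integer_
      comm[v] <- c
      pending <- c(pending, u)
    }
  }
  comm
}

# pair a stub list into simple edges by configuration-model matching;
# conflicting pairs (self-loops, duplicates, forbidden same-group pairs)
# are repaired by partner swaps with random pairs, accepted only when both
# resulting pairs are admissible; irreparable leftovers are dropped
.pairStubs <- function(stubs, forbidSameGroup = NULL, maxTries = 200) {
  stubs <- sample(stubs)
  if (length(stubs) %% 2) stubs <- stubs[-1]
  npair <- length(stubs) / 2
  if (!npair) return(list(edges = cbind(integer(0), integer(0)), dropped = 0))
  a <- stubs[seq_len(npair)]; b <- stubs[npair + seq_len(npair)]
  flag <- function(a, b) {
    bad <- a == b | duplicated(paste(pmin(a, b), pmax(a, b)))
    if (!is.null(forbidSameGroup))
      bad <- bad | forbidSameGroup[a] == forbidSameGroup[b]
    bad
  }
  for (try in seq_len(maxTries)) {
    bad <- flag(a, b)
    if (!any(bad)) break
    for (i in which(bad)) {
      j <- sample.int(npair, 1)
      if (j == i) next
      ok <- a[i] != b[j] && a[j] != b[i]
      if (ok && !is.null(forbidSameGroup))
        ok <- forbidSameGroup[a[i]] != forbidSameGroup[b[j]] &&
              forbidSameGroup[a[j]] != forbidSameGroup[b[i]]
      if (ok) { tmp <- b[i]; b[i] <- b[j]; b[j] <- tmp }
    }
  }
  bad <- flag(a, b)
  lo <- pmin(a, b); hi <- pmax(a, b)
  list(edges = cbind(lo[!bad], hi[!bad]), dropped = 2 * sum(bad))
}

#' Generate an unsigned LFR benchmark graph
#'
#' Power-law degree sequence and community sizes; each node receives
#' approximately `(1 - muOut) * k` internal and `muOut * k` external stubs,
#' wired by a configuration model with conflict repair (self-loops,
#' duplicate edges and internal external-pairs are rewired; irreparable
#' stubs are dropped and reported). The planted community assignment is
#' returned as the ground truth, and the realized (empirical) mixing is
#' reported, since per-node rounding and repair make the nominal `muOut`
#' approximate.
#'
#' @param nNodes number of nodes.
#' @param muOut nominal per-node fraction of links leaving the node's
#'   community, in `[0, 1)`.
#' @param degExponent,comExponent power-law exponents of the degree and
#'   community-size distributions.
#' @param meanDegree,maxDegree target mean and maximum degree; the minimum
#'   degree is solved from the truncated power-law mean.
#' @param minCommunity,maxCommunity community-size bounds.
#' @param seed integer seed; the same spec and seed give an identical
#'   graph.
#' @return A list: `graph` (all-positive [SignedGraph-class]), `truth`
#'   ([Partition-class]), `empirical` (named list: realized mean degree,
#'   mean external fraction, dropped-stub counts).
#' @export
generateLFR <- function(nNodes = 1000, muOut = 0.3, degExponent = 2,
                        comExponent = 1, meanDegree = 20, maxDegree = 50,
                        minCommunity = 20, maxCommunity = 100,
                        seed = NULL) {
  run <- function() {
    if (muOut < 0 || muOut >= 1) stop("muOut must be in [0, 1)")
    kmin <- .solveDegreeMin(degExponent, maxDegree, meanDegree)
    k <- .samplePowerlawInt(nNodes, degExponent, kmin, maxDegree)
    sizes <- .sampleCommunitySizes(nNodes, comExponent, minCommunity,
                                   maxCommunity)
    if (length(sizes) < 2 && muOut > 0)
      stop("infeasible: external mixing requested but only one community fits")
    dInt <- round((1 - muOut) * k)
    if (max(dInt) > max(sizes) - 1)
      stop(sprintf("infeasible: internal degree %d exceeds the largest community size %d - 1",
                   max(dInt), max(sizes)))
    comm <- .assignCommunities(dInt, sizes)
    dInt <- pmin(dInt, sizes[comm] - 1)
    dExt <- k - dInt

    intEdges <- vector("list", length(sizes))
    droppedInt <- 0
    for (c in seq_along(sizes)) {
      members <- which(comm == c)
      d <- dInt[members]
      if (sum(d) %% 2) {
        i <- which.max(d)
        d[i] <- d[i] - 1L
        # keep the node's degree by externalizing the stub, except at zero
        # mixing where the communities must stay disjoint
        if (muOut > 0) dExt[members[i]] <- dExt[members[i]] + 1L
      }
      pr <- .pairStubs(rep(members, d))
      intEdges[[c]] <- pr$edges
      droppedInt <- droppedInt + pr$dropped
    }
    intEdges <- do.call(rbind, intEdges)

    if (sum(dExt) %% 2) {
      i <- which.max(dExt)
      dExt[i] <- dExt[i] - 1L
    }
    prExt <- .pairStubs(rep(seq_len(nNodes), dExt), forbidSameGroup = comm)
    edges <- rbind(intEdges, prExt$edges)

    g <- SignedGraph(posEdges = cbind(edges, 1),
                     nodes = as.character(seq_len(nNodes)))
    kEmp <- unname(posStrength(g))
    extDeg <- numeric(nNodes)
    ext <- prExt$edges
    if (nrow(ext)) {
      t1 <- rowsum(rep(1, 2 * nrow(ext)), c(ext[, 1], ext[, 2]))
      extDeg[as.integer(rownames(t1))] <- t1[, 1]
    }
    list(graph = g,
         truth = Partition(comm, as.character(seq_len(nNodes))),
         empirical = list(
           meanDegree = mean(kEmp),
           muOut = mean(ifelse(kEmp > 0, extDeg / kEmp, 0)),
           droppedInternalStubs = droppedInt,
           droppedExternalStubs = prExt$dropped))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# flip per-node quotas of positive edges of one class (rows of `edges`
# eligible); an edge flipped by either endpoint counts for both.
.flipQuota <- function(edges, nNodes, targets) {
  flipped <- rep(FALSE, nrow(edges))
  if (!nrow(edges) || !any(targets > 0))
    return(list(flipped = flipped, shortfall = 0L))
  incid <- split(rep(seq_len(nrow(edges)), 2),
                 factor(c(edges[, 1], edges[, 2]), levels = seq_len(nNodes)))
  shortfall <- 0L
  cnt <- integer(nNodes)
  other <- function(rows, v) ifelse(edges[rows, 1] == v, edges[rows, 2],
                                    edges[rows, 1])
  for (v in sample.int(nNodes)) {
    need <- targets[v] - cnt[v]
    if (need <= 0) next
    cand <- incid[[v]]
    cand <- cand[!flipped[cand]]
    if (length(cand) < need) {
      shortfall <- shortfall + (need - length(cand))
      need <- length(cand)
    }
    if (!need) next
    # prefer edges whose other endpoint still needs flips: the flip then
    # serves both quotas and the realized fractions track the nominal ones
    o <- other(cand, v)
    needy <- cnt[o] < targets[o]
    cand <- c(cand[needy][sample.int(sum(needy))],
              cand[!needy][sample.int(sum(!needy))])
    pick <- cand[seq_len(need)]
    flipped[pick] <- TRUE
    cnt[edges[pick, 1]] <- cnt[edges[pick, 1]] + 1L
    cnt[edges[pick, 2]] <- cnt[edges[pick, 2]] + 1L
  }
  list(flipped = flipped, shortfall = shortfall)
}

#' Turn an unsigned LFR graph into a signed one
#'
#' Replaces, per node, a `muNegOut` fraction of its links (relative to its
#' degree) by external negative ties and a `muNegIn` fraction by internal
#' negative ties, keeping all endpoints: eligible positive edges of the
#' matching class are flipped to negative. An edge flipped on behalf of one
#' endpoint counts toward the quota of both ("first claim"). With
#' `muOut = 0.6` and `muNegOut = 0.25`, for instance, each node ends up
#' with roughly 40% internal-positive, 25% external-negative and 35%
#' external-positive links.
#'
#' @param g all-positive [SignedGraph-class] from [generateLFR()].
#' @param truth its ground-truth [Partition-class].
#' @param muNegOut,muNegIn per-node fractions of links to turn into
#'   external / internal negative ties; `muNegOut` cannot exceed the
#'   available external fraction (error), while per-node rounding
#'   shortfalls of a link or two are clamped and reported.
#' @param seed integer seed.
#' @return A list: `graph` (signed), `report` (flipped counts and
#'   shortfalls).
#' @export
signifyLFR <- function(g, truth, muNegOut = 0, muNegIn = 0, seed = NULL) {
  run <- function() {
    stopifnot(muNegOut >= 0, muNegIn >= 0, muNegOut + muNegIn <= 1)
    m <- .alignedMembership(g, truth)
    pe <- g@posEdges
    n <- numNodes(g)
    k <- unname(posStrength(g))
    external <- m[pe[, 1]] != m[pe[, 2]]
    doClass <- function(rows, mu) {
      targets <- round(mu * k)
      avail <- numeric(n)
      if (length(rows)) {
        t1 <- rowsum(rep(1, 2 * length(rows)),
                     c(pe[rows, 1], pe[rows, 2]))
        avail[as.integer(rownames(t1))] <- t1[, 1]
      }
      if (sum(targets) > 1.05 * sum(avail) + 2)
        stop("requested negative fraction exceeds the links available in that class")
      fq <- .flipQuota(pe[rows, , drop = FALSE], n, targets)
      list(rows = rows[fq$flipped], shortfall = fq$shortfall)
    }
    fOut <- doClass(which(external), muNegOut)
    fIn <- doClass(which(!external), muNegIn)
    flippedRows <- c(fOut$rows, fIn$rows)
    keep <- setdiff(seq_len(nrow(pe)), flippedRows)
    gs <- SignedGraph(posEdges = pe[keep, , drop = FALSE],
                      negEdges = pe[flippedRows, , drop = FALSE],
                      nodes = g@nodes)
    list(graph = gs,
         report = list(flippedExternal = length(fOut$rows),
                       flippedInternal = length(fIn$rows),
                       shortfallExternal = fOut$shortfall,
                       shortfallInternal = fIn$shortfall))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate a coupled LFR benchmark
#'
#' Two identical copies (layers) of one unsigned LFR graph, so every node
#' and community has a twin. Keeping both layers' internal wiring
#' unchanged, each node `i` is forced to have about `muC * k_i` new
#' positive and `muNegC * k_i` new negative links toward uniformly chosen
#' members of its twin community (never elsewhere, and no duplicates); a
#' node counts links already created toward it, so the realized coupling
#' tracks the nominal one, and the empirical average is reported. When a
#' twin community is too small to host a node's quota the available
#' candidates are used and the shortfall recorded.
#'
#' The reference partitions returned are `single` (every community its own
#' module), `couple` (every community joined with its twin; `single`
#' refines it) and `allInOne`.
#'
#' @inheritParams generateLFR
#' @param muC,muNegC per-node positive / negative coupling fractions in
#'   `[0, 1)`.
#' @return A list: `graph`, `partitions` (list `single`, `couple`,
#'   `allInOne` of [Partition-class]), `empirical` (realized coupling
#'   fractions, shortfalls, layer mixing).
#' @export
generateCoupledLFR <- function(nNodes = 1000, muOut = 0.3, muC = 0,
                               muNegC = 0, degExponent = 2, comExponent = 1,
                               meanDegree = 20, maxDegree = 50,
                               minCommunity = 20, maxCommunity = 100,
                               seed = NULL) {
  run <- function() {
    stopifnot(muC >= 0, muC < 1, muNegC >= 0, muNegC < 1)
    layer <- generateLFR(nNodes = nNodes, muOut = muOut,
                         degExponent = degExponent,
                         comExponent = comExponent, meanDegree = meanDegree,
                         maxDegree = maxDegree, minCommunity = minCommunity,
                         maxCommunity = maxCommunity, seed = NULL)
    n <- nNodes
    comm <- .alignedMembership(layer$graph, layer$truth)
    K <- max(comm)
    e1 <- layer$graph@posEdges[, 1:2, drop = FALSE]
    edges <- rbind(e1, e1 + n)                  # both layers, wiring kept
    nodes <- c(paste0(seq_len(n), "a"), paste0(seq_len(n), "b"))
    commAll <- c(comm, comm)
    layerOf <- rep(1:2, each = n)
    k <- unname(posStrength(layer$graph))

    membersByComm <- split(seq_len(n), comm)
    twinCandidates <- function(v) {
      # members of v's community in the other layer (global ids)
      base <- membersByComm[[comm[(v - 1) %% n + 1]]]
      if (v <= n) base + n else base
    }
    linked <- new.env(parent = emptyenv())     # coupling pairs already used
    pkey <- function(u, v) sprintf("%d_%d", min(u, v), max(u, v))
    posL <- list(); negL <- list()
    degC <- integer(2 * n)                     # realized coupling degree
    degCneg <- integer(2 * n)
    shortfall <- 0L
    kAll <- c(k, k)
    targetPos <- round(muC * kAll); targetNeg <- round(muNegC * kAll)
    addLinks <- function(v, target, have, haveAll, targetAll) {
      need <- target - have
      if (need <= 0) return(integer(0))
      cand <- twinCandidates(v)
      cand <- cand[vapply(cand, function(u)
        is.null(linked[[pkey(v, u)]]), TRUE)]
      if (length(cand) < need) {
        shortfall <<- shortfall + (need - length(cand))
        need <- length(cand)
      }
      if (!need) return(integer(0))
      # prefer twins still short of their own quota so the realized
      # coupling tracks the nominal fraction
      needy <- haveAll[cand] < targetAll[cand]
      cand <- c(cand[needy][sample.int(sum(needy))],
                cand[!needy][sample.int(sum(!needy))])
      cand[seq_len(need)]
    }
    for (v in sample.int(2 * n)) {
      pick <- addLinks(v, targetPos[v], degC[v], degC, targetPos)
      if (length(pick)) {
        for (u in pick) linked[[pkey(v, u)]] <- TRUE
        posL[[length(posL) + 1L]] <- cbind(pmin(v, pick), pmax(v, pick))
        degC[v] <- degC[v] + length(pick)
        degC[pick] <- degC[pick] + 1L
      }
      pick <- addLinks(v, targetNeg[v], degCneg[v], degCneg, targetNeg)
      if (length(pick)) {
        for (u in pick) linked[[pkey(v, u)]] <- TRUE
        negL[[length(negL) + 1L]] <- cbind(pmin(v, pick), pmax(v, pick))
        degCneg[v] <- degCneg[v] + length(pick)
        degCneg[pick] <- degCneg[pick] + 1L
      }
    }
    posC <- if (length(posL)) do.call(rbind, posL) else
      matrix(integer(0), ncol = 2)
    negC <- if (length(negL)) do.call(rbind, negL) else
      matrix(integer(0), ncol = 2)
    g <- SignedGraph(posEdges = cbind(rbind(edges, posC), 1),
                     negEdges = if (nrow(negC)) cbind(negC, 1) else NULL,
                     nodes = nodes)
    single <- Partition(commAll + (layerOf - 1) * K, nodes)
    couple <- Partition(commAll, nodes)
    list(graph = g,
         partitions = list(single = single, couple = couple,
                           allInOne = allInOnePartition(g)),
         empirical = list(
           muC = mean(degC / kAll), muNegC = mean(degCneg / kAll),
           couplingShortfall = shortfall,
           layerMuOut = layer$empirical$muOut,
           layerMeanDegree = layer$empirical$meanDegree))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
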