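#' Accessors for SignedGraph objects
#'
#' `numNodes` and `nodeNames` describe the node set; `posEdges` / `negEdges`
#' return the edge matrices (columns `from`, `to`, `weight`, one row per
#' undirected edge, `from < to`); `posStrength` / `negStrength` return the
#' per-node sums of incident weights; `omegaPos` / `omegaNeg` return the
#' directed weight totals (each undirected edge counted twice).
#'
#' @param x a [SignedGraph-class] object.
#' @name SignedGraph-accessors
NULL

#' @rdname SignedGraph-accessors
#' @export
setMethod("numNodes", "SignedGraph", function(x) length(x@nodes))

#' @rdname SignedGraph-accessors
#' @export
setMethod("nodeNames", "SignedGraph", function(x) x@nodes)

#' @rdname SignedGraph-accessors
#' @export
setMethod("posEdges", "SignedGraph", function(x) x@posEdges)

#' @rdname SignedGraph-accessors
#' @export
setMethod("negEdges", "SignedGraph", function(x) x@negEdges)

.strength <- function(e, n) {
  s <- numeric(n)
  if (nrow(e)) {
    t1 <- rowsum(e[, 3], e[, 1])
    t2 <- rowsum(e[, 3], e[, 2])
    s[as.integer(rownames(t1))] <- t1[, 1]
    s[as.integer(rownames(t2))] <- s[as.integer(rownames(t2))] + t2[, 1]
  }
  s
}

#' @rdname SignedGraph-accessors
#' @export
setMethod("posStrength", "SignedGraph", function(x) {
  s <- .strength(x@posEdges, numNodes(x)); names(s) <- x@nodes; s
})

#' @rdname SignedGraph-accessors
#' @export
setMethod("negStrength", "SignedGraph", function(x) {
  s <- .strength(x@negEdges, numNodes(x)); names(s) <- x@nodes; s
})

#' @rdname SignedGraph-accessors
#' @export
setMethod("omegaPos", "SignedGraph", function(x) 2 * sum(x@posEdges[, 3]))

#' @rdname SignedGraph-accessors
#' @export
setMethod("omegaNeg", "SignedGraph", function(x) 2 * sum(x@negEdges[, 3]))

setMethod("show", "SignedGraph", function(object) {
  cat(sprintf(
    "SignedGraph: %d nodes, %d positive and %d negative edges\n",
    numNodes(object), nrow(object@posEdges), nrow(object@negEdges)))
  invisible(object)
})

#' Positive subgraph
#'
#' Drops all negative edges, keeping the full node set.
#'
#' @param g a [SignedGraph-class].
#' @return A [SignedGraph-class] with `omegaNeg(g) == 0`.
#' @export
positiveSubgraph <- function(g) {
  new("SignedGraph", nodes = g@nodes, posEdges = g@posEdges,
      negEdges = .emptyEdges())
}

# Net-weight edges (w+ - w-) as a single signed matrix; pairs carry only one
# sign by the SignedGraph invariant, so this is a concatenation.
.netEdges <- function(g) {
  ne <- g@negEdges
  if (nrow(ne)) ne[, 3] <- -ne[, 3]
  rbind(g@posEdges, ne)
}

# ---------------------------------------------------------------------------
# Edge-list I/O

.parseEdgeTokens <- function(path) {
  lines <- readLines(path)
  raw <- trimws(lines)
  keep <- nzchar(raw) & !startsWith(raw, "#")
  lineno <- which(keep)
  raw <- raw[keep]
  if (!length(raw))
    return(data.frame(from = character(), to = character(),
                      weight = numeric(), line = integer()))
  toks <- strsplit(raw, "[[:space:]]+")
  nf <- lengths(toks)
  if (any(nf < 3))
    stop(sprintf("malformed edge list line %d: '%s' (need source target weight)",
                 lineno[which(nf < 3)[1]], raw[which(nf < 3)[1]]))
  from <- vapply(toks, `[[`, "", 1L)
  to <- vapply(toks, `[[`, "", 2L)
  wtok <- vapply(toks, `[[`, "", 3L)
  # unicode minus occasionally appears in exported sign columns
  wtok <- gsub("−", "-", wtok)
  w <- suppressWarnings(as.numeric(wtok))
  w[wtok == "+"] <- 1
  w[wtok == "-"] <- -1
  if (anyNA(w))
    stop(sprintf("malformed weight on line %d: '%s'",
                 lineno[which(is.na(w))[1]], raw[which(is.na(w))[1]]))
  if (any(w == 0))
    stop(sprintf("zero weight on line %d", lineno[which(w == 0)[1]]))
  data.frame(from = from, to = to, weight = w, line = lineno,
             stringsAsFactors = FALSE)
}

#' Read a signed edge list
#'
#' Parses a whitespace-separated text edge list (`source target weight`,
#' `#` comments; the weight field may be a signed number or a bare `+` / `-`
#' token meaning +/-1), the format used by SNAP `soc-sign` exports.
#'
#' In undirected mode (the default) the two orientations of a pair are
#' merged by summing their weights; a pair whose lines carry both signs is
#' an error (read with `directed = TRUE` and run
#' [preprocessSignedGraph()] instead, which resolves such conflicts by the
#' documented rules). Self-loops are skipped with a warning.
#'
#' @param path path to the edge-list file.
#' @param directed if `TRUE`, return the raw directed edge set (a
#'   data.frame of class `directedEdgeSet` with columns `from`, `to`,
#'   `weight`) for later preprocessing.
#' @return A [SignedGraph-class], or a `directedEdgeSet` data.frame.
#' @export
readEdgeList <- function(path, directed = FALSE) {
  ed <- .parseEdgeTokens(path)
  nself <- sum(ed$from == ed$to)
  if (nself) {
    warning(sprintf("skipped %d self-loop(s)", nself))
    ed <- ed[ed$from != ed$to, , drop = FALSE]
  }
  if (directed) {
    out <- ed[, c("from", "to", "weight")]
    class(out) <- c("directedEdgeSet", "data.frame")
    return(out)
  }
  nodes <- sort(unique(c(ed$from, ed$to)))
  if (!length(nodes))
    return(SignedGraph(nodes = character(0)))
  i <- match(ed$from, nodes); j <- match(ed$to, nodes)
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- paste(lo, hi)
  wsum <- rowsum(ed$weight, key)
  signs <- tapply(sign(ed$weight), key, function(s) length(unique(s)))
  if (any(signs > 1)) {
    bad <- names(signs)[signs > 1][1]
    stop(sprintf("pair (%s) carries edges of both signs; read with directed = TRUE and preprocess",
                 paste(nodes[as.integer(strsplit(bad, " ")[[1]])], collapse = ", ")))
  }
  ij <- do.call(rbind, lapply(strsplit(rownames(wsum), " "), as.integer))
  w <- wsum[, 1]
  keep <- w != 0
  ij <- ij[keep, , drop = FALSE]; w <- w[keep]
  SignedGraph(posEdges = cbind(ij, w)[w > 0, , drop = FALSE],
              negEdges = cbind(ij, -w)[w < 0, , drop = FALSE],
              nodes = nodes)
}

#' Write a signed edge list
#'
#' Inverse of [readEdgeList()]: one `source target weight` line per
#' undirected edge, negative edges written with negative weights.
#'
#' @param g a [SignedGraph-class].
#' @param path output file path.
#' @export
writeEdgeList <- function(g, path) {
  e <- .netEdges(g)
  lines <- sprintf("%s\t%s\t%g", g@nodes[e[, 1]], g@nodes[e[, 2]], e[, 3])
  writeLines(c("# source\ttarget\tweight", lines), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Preprocessing (raw directed signed networks -> analysis-ready graph)

.largestComponent <- function(nodes, edgePairs) {
  i <- match(edgePairs[, 1], nodes)
  j <- match(edgePairs[, 2], nodes)
  ig <- igraph::make_empty_graph(length(nodes), directed = FALSE)
  ig <- igraph::add_edges(ig, as.vector(t(cbind(i, j))))
  comp <- igraph::components(ig)
  nodes[comp$membership == which.max(comp$csize)]
}

#' Preprocess a raw signed network
#'
#' Applies, in order, the three standard cleaning rules for raw directed
#' signed social networks: (1) both members of every reciprocal pair of
#' links whose signs disagree are dropped and the surviving links are
#' treated as undirected (a consistent reciprocal pair collapses to a
#' single undirected edge); (2) only the largest connected component is
#' kept, where connectivity is taken over the union of positive and
#' negative edges; (3) nodes incident to zero positive edges are removed
#' (they trivially form isolated clusters), and the largest component is
#' re-taken once if the removal disconnected the graph.
#'
#' Repeated lines for the same directed pair are first aggregated by
#' summing; a pair whose aggregated forward and backward weights agree in
#' sign is averaged into one undirected weight, and an unordered pair
#' netting to zero is dropped.
#'
#' @param x a `directedEdgeSet` (from `readEdgeList(path, directed = TRUE)`)
#'   or a [SignedGraph-class] (steps 2-3 only; applying the function to its
#'   own output is then a no-op).
#' @return A list with elements `graph` (the cleaned [SignedGraph-class])
#'   and `report` (named list of per-step counts and fractions).
#' @export
preprocessSignedGraph <- function(x) {
  report <- list()
  if (inherits(x, "directedEdgeSet")) {
    nDirected <- nrow(x)
    # aggregate repeated directed pairs by net weight
    key <- paste(x$from, x$to, sep = "\r")
    w <- rowsum(x$weight, key)
    parts <- strsplit(rownames(w), "\r", fixed = TRUE)
    from <- vapply(parts, `[[`, "", 1L)
    to <- vapply(parts, `[[`, "", 2L)
    w <- w[, 1]
    keep <- w != 0
    from <- from[keep]; to <- to[keep]; w <- w[keep]
    # reciprocal pairs: same unordered pair seen in both directions
    lo <- pmin(from, to); hi <- pmax(from, to)
    ukey <- paste(lo, hi, sep = "\r")
    dup <- ukey %in% ukey[duplicated(ukey)]
    consistent <- rep(TRUE, length(w))
    if (any(dup)) {
      sgn <- tapply(sign(w)[dup], ukey[dup], function(s) length(unique(s)))
      badKeys <- names(sgn)[sgn > 1]
      consistent[ukey %in% badKeys] <- FALSE
    }
    report$inconsistentLinks <- sum(!consistent)
    report$inconsistentFraction <-
      if (nDirected) sum(!consistent) / nDirected else 0
    from <- from[consistent]; to <- to[consistent]; w <- w[consistent]
    ukey <- ukey[consistent]
    # collapse to undirected: mean weight over the (1 or 2) directions
    uw <- tapply(w, ukey, mean)
    parts <- strsplit(names(uw), "\r", fixed = TRUE)
    ed <- data.frame(from = vapply(parts, `[[`, "", 1L),
                     to = vapply(parts, `[[`, "", 2L),
                     weight = as.numeric(uw), stringsAsFactors = FALSE)
    if (!nrow(ed)) stop("preprocessing removed every edge")
    nodes <- sort(unique(c(ed$from, ed$to)))
    g <- SignedGraph(
      posEdges = cbind(match(ed$from, nodes), match(ed$to, nodes),
                       abs(ed$weight))[ed$weight > 0, , drop = FALSE],
      negEdges = cbind(match(ed$from, nodes), match(ed$to, nodes),
                       abs(ed$weight))[ed$weight < 0, , drop = FALSE],
      nodes = nodes)
  } else if (is(x, "SignedGraph")) {
    g <- x
    report$inconsistentLinks <- 0L
    report$inconsistentFraction <- 0
  } else stop("x must be a directedEdgeSet or a SignedGraph")

  report$nodesBeforeComponent <- numNodes(g)
  # step 2: largest connected component over the pos/neg union
  e <- rbind(g@posEdges, g@negEdges)
  if (!nrow(e)) stop("preprocessing removed every edge")
  keepNodes <- .largestComponent(g@nodes, cbind(g@nodes[e[, 1]],
                                                g@nodes[e[, 2]]))
  g <- .inducedSubgraph(g, keepNodes)
  report$componentNodeFraction <- numNodes(g) / report$nodesBeforeComponent

  # step 3: drop zero-positive nodes, then re-take the component once
  zp <- posStrength(g) == 0
  report$zeroPositiveRemoved <- sum(zp)
  if (any(zp)) {
    g <- .inducedSubgraph(g, g@nodes[!zp])
    e <- rbind(g@posEdges, g@negEdges)
    if (!nrow(e)) stop("preprocessing removed every edge")
    keepNodes <- .largestComponent(g@nodes, cbind(g@nodes[e[, 1]],
                                                  g@nodes[e[, 2]]))
    g <- .inducedSubgraph(g, keepNodes)
  }
  report$finalNodes <- numNodes(g)
  report$finalPosEdges <- nrow(g@posEdges)
  report$finalNegEdges <- nrow(g@negEdges)
  report$negativeEdgeFraction <-
    report$finalNegEdges / max(1L, report$finalPosEdges + report$finalNegEdges)
  list(graph = g, report = report)
}

.inducedSubgraph <- function(g, keepNodes) {
  idx <- match(keepNodes, g@nodes)
  newId <- rep(NA_integer_, numNodes(g))
  newId[idx] <- seq_along(idx)
  sub <- function(e) {
    keep <- !is.na(newId[e[, 1]]) & !is.na(newId[e[, 2]])
    e <- e[keep, , drop = FALSE]
    e[, 1] <- newId[e[, 1]]; e[, 2] <- newId[e[, 2]]
    e
  }
  SignedGraph(posEdges = sub(g@posEdges), negEdges = sub(g@negEdges),
              nodes = g@nodes[idx])
}

# ---------------------------------------------------------------------------
# Partition accessors, helpers and I/O

#' Accessors for Partition objects
#'
#' @param x a [Partition-class].
#' @name Partition-accessors
NULL

#' @rdname Partition-accessors
#' @export
setMethod("membership", "Partition", function(x) {
  m <- x@membership; names(m) <- x@nodes; m
})

#' @rdname Partition-accessors
#' @export
setMethod("nModules", "Partition", function(x) {
  if (length(x@membership)) max(x@membership) else 0L
})

#' @rdname Partition-accessors
#' @export
setMethod("moduleSizes", "Partition", function(x) {
  tabulate(x@membership, nModules(x))
})

setMethod("show", "Partition", function(object) {
  cat(sprintf("Partition: %d nodes in %d modules\n",
              length(object@membership), nModules(object)))
  invisible(object)
})

#' Trivial partitions
#'
#' `allInOnePartition` places every node in a single module;
#' `singletonPartition` places every node in its own module.
#'
#' @param g a [SignedGraph-class] (or a character vector of node labels).
#' @return A [Partition-class].
#' @export
allInOnePartition <- function(g) {
  nodes <- if (is.character(g)) g else nodeNames(g)
  Partition(rep(1L, length(nodes)), nodes)
}

#' @rdname allInOnePartition
#' @export
singletonPartition <- function(g) {
  nodes <- if (is.character(g)) g else nodeNames(g)
  Partition(seq_along(nodes), nodes)
}

# membership aligned to a graph's node order
.alignedMembership <- function(g, p) {
  idx <- match(g@nodes, p@nodes)
  if (anyNA(idx))
    stop(sprintf("partition is missing node '%s'", g@nodes[which(is.na(idx))[1]]))
  p@membership[idx]
}

#' Per-module summaries of a partitioned signed graph
#'
#' @param g a [SignedGraph-class].
#' @param p a [Partition-class] over the same node set.
#' @return data.frame with one row per module: node count `n`, directed
#'   internal weights `wPosIn` / `wNegIn` (each internal undirected edge
#'   counted twice), and boundary weights `wPosOut` / `wNegOut`.
#' @export
moduleSummaries <- function(g, p) {
  m <- .alignedMembership(g, p)
  k <- max(m)
  agg <- function(e, strength) {
    internal <- numeric(k)
    if (nrow(e)) {
      same <- m[e[, 1]] == m[e[, 2]]
      if (any(same)) {
        t <- rowsum(2 * e[same, 3], m[e[same, 1]])
        internal[as.integer(rownames(t))] <- t[, 1]
      }
    }
    stot <- numeric(k)
    t <- rowsum(strength, m)
    stot[as.integer(rownames(t))] <- t[, 1]
    list(internal = internal, out = stot - internal)
  }
  ap <- agg(g@posEdges, unname(posStrength(g)))
  an <- agg(g@negEdges, unname(negStrength(g)))
  data.frame(module = seq_len(k), n = tabulate(m, k),
             wPosIn = ap$internal, wNegIn = an$internal,
             wPosOut = ap$out, wNegOut = an$out)
}

#' Read and write partition files
#'
#' Two-column whitespace-separated text format: `node module`, one line per
#' node; `#` comments allowed. Round-tripping a partition through a file is
#' the identity.
#'
#' @param p a [Partition-class].
#' @param path file path.
#' @param graph optional [SignedGraph-class]; when given, the file must
#'   cover exactly the graph's nodes (an unknown or missing node is an
#'   error) and the result follows the graph's node order.
#' @return `readPartition` returns a [Partition-class]; `writePartition`
#'   invisibly returns `path`.
#' @export
writePartition <- function(p, path) {
  writeLines(sprintf("%s\t%d", p@nodes, p@membership), path)
  invisible(path)
}

#' @rdname writePartition
#' @export
readPartition <- function(path, graph = NULL) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "[[:space:]]+")
  if (any(lengths(toks) < 2))
    stop("malformed partition file: need 'node module' per line")
  nodes <- vapply(toks, `[[`, "", 1L)
  mods <- vapply(toks, `[[`, "", 2L)
  if (anyDuplicated(nodes))
    stop(sprintf("node '%s' listed twice", nodes[duplicated(nodes)][1]))
  p <- Partition(mods, nodes)
  if (!is.null(graph)) {
    unknown <- setdiff(nodes, nodeNames(graph))
    if (length(unknown))
      stop(sprintf("partition file names unknown node '%s'", unknown[1]))
    p <- Partition(.alignedMembership(graph, p), nodeNames(graph))
  }
  p
}
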