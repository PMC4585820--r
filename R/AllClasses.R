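#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib CPMap, .registration = TRUE
NULL

#' Signed graph
#'
#' An undirected, weighted graph whose edges are split into a positive and a
#' negative subgraph. Negative weights are stored as magnitudes. Edge
#' endpoints are 1-based indices into `nodes`; every edge is stored once with
#' `from < to`, so all "directed" totals (e.g. [omegaPos()]) count each
#' undirected edge twice.
#'
#' @slot nodes character vector of node labels.
#' @slot posEdges numeric matrix with columns `from`, `to`, `weight`
#'   (positive subgraph).
#' @slot negEdges numeric matrix with columns `from`, `to`, `weight`
#'   (negative subgraph, weights are magnitudes).
#'
#' @seealso [SignedGraph()], [readEdgeList()], [preprocessSignedGraph()]
#' @exportClass SignedGraph
setClass("SignedGraph",
  representation(nodes = "character", posEdges = "matrix",
                 negEdges = "matrix"))

.emptyEdges <- function() {
  matrix(numeric(0), ncol = 3,
         dimnames = list(NULL, c("from", "to", "weight")))
}

.checkEdgeMatrix <- function(e, n, what) {
  if (ncol(e) != 3) return(sprintf("%s must have 3 columns", what))
  if (nrow(e) == 0) return(NULL)
  i <- e[, 1]; j <- e[, 2]; w <- e[, 3]
  if (any(i != round(i)) || any(j != round(j)))
    return(sprintf("%s endpoints must be integer indices", what))
  if (any(i < 1) || any(j < 1) || any(i > n) || any(j > n))
    return(sprintf("%s endpoints out of range", what))
  if (any(i == j)) return(sprintf("%s contains self-loops", what))
  if (any(i > j)) return(sprintf("%s must be stored with from < to", what))
  if (any(w <= 0)) return(sprintf("%s weights must be strictly positive", what))
  if (anyDuplicated(i * (n + 1) + j))
    return(sprintf("%s contains duplicate edges", what))
  NULL
}

setValidity("SignedGraph", function(object) {
  n <- length(object@nodes)
  if (anyDuplicated(object@nodes)) return("duplicate node labels")
  msg <- .checkEdgeMatrix(object@posEdges, n, "posEdges")
  if (!is.null(msg)) return(msg)
  msg <- .checkEdgeMatrix(object@negEdges, n, "negEdges")
  if (!is.null(msg)) return(msg)
  if (nrow(object@posEdges) && nrow(object@negEdges)) {
    kp <- object@posEdges[, 1] * (n + 1) + object@posEdges[, 2]
    kn <- object@negEdges[, 1] * (n + 1) + object@negEdges[, 2]
    if (any(kp %in% kn))
      return("a node pair carries both a positive and a negative weight")
  }
  TRUE
})

#' Construct a SignedGraph
#'
#' @param posEdges,negEdges numeric matrices (or data.frames) with columns
#'   `from`, `to`, `weight`; endpoints may be given in either order and are
#'   normalised to `from < to`. `NULL` means no edges of that sign.
#' @param nodes character vector of node labels; defaults to
#'   `as.character(seq_len(n))` where `n` is inferred from the edges.
#' @return A [SignedGraph-class] object.
#' @examples
#' g <- SignedGraph(posEdges = cbind(c(1, 2), c(2, 3), 1),
#'                  negEdges = cbind(1, 3, 1))
#' g
#' @export
SignedGraph <- function(posEdges = NULL, negEdges = NULL, nodes = NULL) {
  fix <- function(e) {
    if (is.null(e) || NROW(e) == 0) return(.emptyEdges())
    e <- as.matrix(e)
    storage.mode(e) <- "double"
    swap <- e[, 1] > e[, 2]
    if (any(swap)) e[swap, 1:2] <- e[swap, 2:1]
    o <- order(e[, 1], e[, 2])
    e <- e[o, , drop = FALSE]
    colnames(e) <- c("from", "to", "weight")
    e
  }
  pe <- fix(posEdges); ne <- fix(negEdges)
  if (is.null(nodes)) {
    n <- max(0, pe[, 1:2], ne[, 1:2])
    nodes <- as.character(seq_len(n))
  }
  new("SignedGraph", nodes = as.character(nodes), posEdges = pe,
      negEdges = ne)
}

#' Partition of a graph's nodes into modules
#'
#' Module ids are compacted to the contiguous range `1..nModules` on
#' construction (ordered by first appearance of the original labels in
#' sorted order).
#'
#' @slot membership integer vector, one module id per node.
#' @slot nodes character vector of node labels, parallel to `membership`.
#' @seealso [Partition()], [membership()], [nvi()]
#' @exportClass Partition
setClass("Partition",
  representation(membership = "integer", nodes = "character"))

setValidity("Partition", function(object) {
  if (length(object@membership) != length(object@nodes))
    return("membership and nodes differ in length")
  if (anyDuplicated(object@nodes)) return("duplicate node labels")
  if (length(object@membership)) {
    k <- max(object@membership)
    if (min(object@membership) < 1 ||
        !identical(sort(unique(object@membership)), seq_len(k)))
      return("module ids must be contiguous 1..K")
  }
  TRUE
})

#' Construct a Partition
#'
#' @param membership vector of module labels (any type), one per node; names
#'   are used as node labels when `nodes` is missing.
#' @param nodes character vector of node labels.
#' @return A [Partition-class] object with compacted integer module ids.
#' @examples
#' Partition(c(a = 1, b = 1, c = 2))
#' @export
Partition <- function(membership, nodes = names(membership)) {
  if (is.null(nodes)) nodes <- as.character(seq_along(membership))
  m <- match(membership, sort(unique(membership)))
  new("Partition", membership = as.integer(m), nodes = as.character(nodes))
}

#' Reweighted random-walk flows on a signed graph
#'
#' Per-node transition probabilities over positive links after the signed
#' reweighting (see [reweightFlows()]), the backflow redirected from
#' cancelled inter-module links, and the negative-teleport mass.
#'
#' @slot trans sparse transition matrix (row i gives the reweighted
#'   probabilities out of node i; rows sum to `1 - teleport`).
#' @slot teleport per-node negative-teleport mass (spread uniformly over all
#'   nodes when walking).
#' @slot backflow per-node probability mass redirected from inter-module
#'   links back onto internal links.
#' @slot membership partition under which the flows were computed.
#' @slot posStrength positive strengths of the underlying graph (used for
#'   smart-teleportation weights).
#' @slot nodes node labels.
#' @exportClass FlowModel
setClass("FlowModel",
  representation(trans = "dgCMatrix", teleport = "numeric",
                 backflow = "numeric", membership = "integer",
                 posStrength = "numeric", nodes = "character"))

#' Stationary visit distribution of the reweighted walk
#'
#' @slot pVisit stationary per-node visit rates (after the final
#'   teleport-free smart-teleportation step).
#' @slot qExit per-module exit (= entry) probabilities, teleport-free.
#' @slot tau teleportation rate used during power iteration.
#' @slot teleportWeights smart-teleportation target weights.
#' @slot iterations number of power-iteration steps performed.
#' @slot residual final L1 change between successive iterates.
#' @exportClass VisitDistribution
setClass("VisitDistribution",
  representation(pVisit = "numeric", qExit = "numeric", tau = "numeric",
                 teleportWeights = "numeric", iterations = "integer",
                 residual = "numeric"))

#' A scan of the CPM resolution spectrum
#'
#' @slot table data.frame with one row per resolution: `lambda`, `mdl`
#'   (SiMap description length in bits), `cpm` (optimized signed CPM value),
#'   `nModules`, `intNegRatio`, `intPosRatio` (fractions of negative /
#'   positive weight internal to modules).
#' @slot partitions list of [Partition-class] objects, parallel to the rows
#'   of `table`.
#' @exportClass SpectrumScan
setClass("SpectrumScan",
  representation(table = "data.frame", partitions = "list"))
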