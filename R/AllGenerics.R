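#' @rdname SignedGraph-accessors
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname SignedGraph-accessors
#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))

#' @rdname SignedGraph-accessors
#' @export
setGeneric("posEdges", function(x) standardGeneric("posEdges"))

#' @rdname SignedGraph-accessors
#' @export
setGeneric("negEdges", function(x) standardGeneric("negEdges"))

#' @rdname SignedGraph-accessors
#' @export
setGeneric("posStrength", function(x) standardGeneric("posStrength"))

#' @rdname SignedGraph-accessors
#' @export
setGeneric("negStrength", function(x) standardGeneric("negStrength"))

#' @rdname SignedGraph-accessors
#' @export
setGeneric("omegaPos", function(x) standardGeneric("omegaPos"))

#' @rdname SignedGraph-accessors
#' @export
setGeneric("omegaNeg", function(x) standardGeneric("omegaNeg"))

#' @rdname Partition-accessors
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))

#' @rdname Partition-accessors
#' @export
setGeneric("nModules", function(x) standardGeneric("nModules"))

#' @rdname Partition-accessors
#' @export
setGeneric("moduleSizes", function(x) standardGeneric("moduleSizes"))
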