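#' @rdname accessors
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname accessors
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @rdname accessors
#' @export
setGeneric("weightMatrix", function(x) standardGeneric("weightMatrix"))

#' @rdname accessors
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' @rdname accessors
#' @export
setGeneric("sparsity", function(x) standardGeneric("sparsity"))

#' @rdname accessors
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))

#' @rdname accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname accessors
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @rdname accessors
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))

#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname accessors
#' @export
setGeneric("hubSet", function(x) standardGeneric("hubSet"))

#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname accessors
#' @export
setGeneric("phiTable", function(x) standardGeneric("phiTable"))
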