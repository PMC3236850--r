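#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Small accessor layer over the package classes so user code never touches
#' slots directly.
#'
#' @param x an object of one of the package classes.
#' @param ... passed to methods.
#' @return `vertices`: character vector of vertex IDs; `edges`: two-column
#'   character matrix of canonical edges; `numVertices`/`numEdges`: integer
#'   counts; `networkName`: the label; `vertexDegree`: named integer vector
#'   (or single integer for one vertex); `clusters`: list of character
#'   vectors; `unclassified`: named character vector of hub/outlier labels;
#'   `geneSets`: named list of gene sets; `universe`: character vector;
#'   `scanParams`: a [ScanParams-class]; `profileRows`: a data.frame;
#'   `chosenK`: integer; `voteCounts`: data.frame.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("vertices", function(x, ...) standardGeneric("vertices"))

#' @rdname accessors
#' @export
setGeneric("edges", function(x, ...) standardGeneric("edges"))

#' @rdname accessors
#' @export
setGeneric("numVertices", function(x) standardGeneric("numVertices"))

#' @rdname accessors
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname accessors
#' @export
setGeneric("networkName", function(x) standardGeneric("networkName"))

#' @rdname accessors
#' @export
setGeneric("vertexDegree", function(x, v = NULL) standardGeneric("vertexDegree"))

#' @rdname accessors
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))

#' @rdname accessors
#' @export
setGeneric("unclassified", function(x) standardGeneric("unclassified"))

#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname accessors
#' @export
setGeneric("universe", function(x) standardGeneric("universe"))

#' @rdname accessors
#' @export
setGeneric("scanParams", function(x) standardGeneric("scanParams"))

#' @rdname accessors
#' @export
setGeneric("profileRows", function(x) standardGeneric("profileRows"))

#' @rdname accessors
#' @export
setGeneric("chosenK", function(x) standardGeneric("chosenK"))

#' @rdname accessors
#' @export
setGeneric("voteCounts", function(x) standardGeneric("voteCounts"))
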