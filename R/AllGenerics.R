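#' @include RcppExports.R
NULL

#' Accessor generics for tessellation and tracking objects
#'
#' Standard accessors for the S4 classes in this package. All accessors
#' return base R objects (vectors, matrices, data frames) so that results
#' can be fed directly into downstream analyses.
#'
#' @param x an object of the appropriate class
#' @param ... further arguments passed to methods
#' @name epimcs-generics
NULL

#' @rdname epimcs-generics
#' @export
setGeneric("cellIds", function(x, ...) standardGeneric("cellIds"))

#' @rdname epimcs-generics
#' @export
setGeneric("nCells", function(x, ...) standardGeneric("nCells"))

#' @rdname epimcs-generics
#' @export
setGeneric("vertexCoords", function(x, ...) standardGeneric("vertexCoords"))

#' @rdname epimcs-generics
#' @export
setGeneric("cellPolygons", function(x, ...) standardGeneric("cellPolygons"))

#' @rdname epimcs-generics
#' @export
setGeneric("cellCentroids", function(x, ...) standardGeneric("cellCentroids"))

#' @rdname epimcs-generics
#' @export
setGeneric("cellAreas", function(x, ...) standardGeneric("cellAreas"))

#' @rdname epimcs-generics
#' @export
setGeneric("boundaryCells", function(x, ...) standardGeneric("boundaryCells"))

#' @rdname epimcs-generics
#' @export
setGeneric("meanCellLength", function(x, ...) standardGeneric("meanCellLength"))

#' @rdname epimcs-generics
#' @export
setGeneric("cellNetwork", function(x, ...) standardGeneric("cellNetwork"))

#' @rdname epimcs-generics
#' @export
setGeneric("mappingPairs", function(x, ...) standardGeneric("mappingPairs"))

#' @rdname epimcs-generics
#' @export
setGeneric("trackedMapping", function(x, ...) standardGeneric("trackedMapping"))

#' @rdname epimcs-generics
#' @export
setGeneric("divisions", function(x, ...) standardGeneric("divisions"))

#' @rdname epimcs-generics
#' @export
setGeneric("deaths", function(x, ...) standardGeneric("deaths"))

#' @rdname epimcs-generics
#' @export
setGeneric("untrackedCells", function(x, ...) standardGeneric("untrackedCells"))

#' @rdname epimcs-generics
#' @export
setGeneric("truthMap", function(x, ...) standardGeneric("truthMap"))
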