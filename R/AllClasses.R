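#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## CellMesh
## ---------------------------------------------------------------------------

#' Polygonal tessellation of an epithelial sheet
#'
#' A `CellMesh` stores the polygonal approximation of a segmented frame:
#' vertices at the junctions where three or more cells meet, and one simple
#' polygon per cell, given as an ordered (counter-clockwise) list of vertex
#' ids. The dual cell-adjacency network is derived from the mesh with
#' [cellNetwork()]: two cells are adjacent if and only if their polygons
#' share at least one edge.
#'
#' Coordinates are in length units for synthetic tissues (average cell area
#' is close to 1, so one unit is about one cell length) and in pixels for
#' meshes extracted from label images.
#'
#' @slot vertices numeric matrix with two columns (`x`, `y`); row names are
#'   the vertex ids.
#' @slot cells named list; each element is an integer vector of vertex ids
#'   in counter-clockwise order, the name is the integer cell id
#'   (frame-local).
#'
#' @seealso [cellMesh()], [cellNetwork()], [generateTissue()],
#'   [meshFromLabelImage()]
#' @export
setClass("CellMesh",
    representation(vertices = "matrix", cells = "list"))

setValidity("CellMesh", function(object) {
    v <- object@vertices
    msg <- character()
    if (ncol(v) != 2L || !is.numeric(v))
        msg <- c(msg, "'vertices' must be a numeric matrix with 2 columns")
    if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
        msg <- c(msg, "vertex ids (rownames) must be present and unique")
    if (length(v) && !all(is.finite(v)))
        msg <- c(msg, "vertex positions must be finite")
    cl <- object@cells
    if (is.null(names(cl)) || anyDuplicated(names(cl)))
        msg <- c(msg, "cell ids (names) must be present and unique")
    if (length(msg)) return(msg)
    if (length(cl)) {
        nv <- lengths(cl)
        if (any(nv < 3L))
            msg <- c(msg, "every cell needs at least 3 vertices")
        vids <- rownames(v)
        if (!all(as.character(unlist(cl, use.names = FALSE)) %in% vids))
            msg <- c(msg, "cells reference unknown vertex ids")
        if (length(msg)) return(msg)
        areas <- vapply(cl, function(ids) {
            p <- v[as.character(ids), , drop = FALSE]
            .polygonArea(p)
        }, numeric(1))
        if (any(areas <= 0))
            msg <- c(msg, "cell polygons must have positive area (CCW order)")
        ## an edge may be shared by at most two cells
        ed <- .meshEdgeTable(object)
        if (nrow(ed)) {
            cnt <- table(ed$key)
            if (any(cnt > 2L))
                msg <- c(msg, "mesh has a polygon edge shared by more than 2 cells")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Construct a CellMesh
#'
#' Builds a validated [CellMesh-class] from vertex coordinates and per-cell
#' vertex lists. Polygon orientation is normalised to counter-clockwise.
#'
#' @param vertices a data frame with columns `id`, `x`, `y`, or a numeric
#'   two-column matrix whose row names are vertex ids.
#' @param cells named list of integer vertex-id vectors; names are cell ids.
#' @return a `CellMesh` object
#' @examples
#' vs <- data.frame(id = 1:4, x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
#' # a single square cell
#' m <- cellMesh(vs, list(`1` = c(1, 2, 3, 4)))
#' cellAreas(m)
#' @export
cellMesh <- function(vertices, cells) {
    if (is.data.frame(vertices)) {
        vm <- as.matrix(vertices[, c("x", "y")])
        rownames(vm) <- as.character(as.integer(vertices$id))
    } else {
        vm <- vertices
        storage.mode(vm) <- "double"
    }
    colnames(vm) <- c("x", "y")
    cells <- lapply(cells, as.integer)
    ## normalise orientation to CCW
    cells <- lapply(cells, function(ids) {
        p <- vm[as.character(ids), , drop = FALSE]
        if (.polygonSignedArea(p) < 0) rev(ids) else ids
    })
    names(cells) <- as.character(as.integer(names(cells)))
    new("CellMesh", vertices = vm, cells = cells)
}

setMethod("show", "CellMesh", function(object) {
    cat("CellMesh with", length(object@cells), "cells and",
        nrow(object@vertices), "vertices\n")
    if (length(object@cells)) {
        a <- cellAreas(object)
        cat(sprintf("  mean cell area %.3f, mean cell length %.3f\n",
                    mean(a), meanCellLength(object)))
        r <- apply(object@vertices, 2, range)
        cat(sprintf("  bounding box [%.2f, %.2f] x [%.2f, %.2f]\n",
                    r[1, 1], r[2, 1], r[1, 2], r[2, 2]))
    }
})

## ---------------------------------------------------------------------------
## TrackerConfig
## ---------------------------------------------------------------------------

#' Tracker configuration
#'
#' Parameters controlling the maximum-common-subgraph tracker. The defaults
#' are deliberately permissive and are not tissue-specific; they are the
#' values used throughout the validation suite.
#'
#' @slot dMax maximum centroid displacement (in units of the first frame's
#'   mean cell length, see [meanCellLength()]) for a candidate cell pair.
#' @slot minConnections minimum number of tracked neighbours with preserved
#'   adjacency a pair must have to survive the cleaning step.
#' @slot minClusterSize minimum size of a connected tracked cluster kept by
#'   the cleaning step (clusters strictly smaller are discarded).
#' @slot postMinNeighbours minimum number of preserved tracked-neighbour
#'   connections required to add a pair during post-processing.
#' @export
setClass("TrackerConfig",
    representation(dMax = "numeric", minConnections = "integer",
                   minClusterSize = "integer", postMinNeighbours = "integer"))

setValidity("TrackerConfig", function(object) {
    if (object@dMax <= 0 || object@minConnections < 1L ||
        object@minClusterSize < 1L || object@postMinNeighbours < 1L)
        "all configuration values must be positive" else TRUE
})

#' @param dMax,minConnections,minClusterSize,postMinNeighbours see the
#'   corresponding slots.
#' @return `trackerConfig()` returns a `TrackerConfig` object.
#' @rdname TrackerConfig-class
#' @examples
#' trackerConfig()
#' @export
trackerConfig <- function(dMax = 10, minConnections = 3L,
                          minClusterSize = 11L, postMinNeighbours = 2L) {
    new("TrackerConfig", dMax = as.numeric(dMax),
        minConnections = as.integer(minConnections),
        minClusterSize = as.integer(minClusterSize),
        postMinNeighbours = as.integer(postMinNeighbours))
}

setMethod("show", "TrackerConfig", function(object) {
    cat("TrackerConfig: dMax =", object@dMax,
        "cell lengths, minConnections =", object@minConnections,
        ", minClusterSize =", object@minClusterSize,
        ", postMinNeighbours =", object@postMinNeighbours, "\n")
})

## ---------------------------------------------------------------------------
## CellMapping
## ---------------------------------------------------------------------------

#' Partial cell-to-cell correspondence between two frames
#'
#' A `CellMapping` is an injective partial map from the cell ids of one
#' frame to the cell ids of the next. Each pair carries a provenance tag
#' stating which stage of the tracker produced it: `"seed"` (the initial
#' match), `"mcs"` (iterative maximum-common-subgraph extension) or
#' `"post"` (adjacency-guided post-processing).
#'
#' @slot pairs data.frame with integer columns `from`, `to` and character
#'   column `provenance`.
#' @seealso [track()], [extendMCS()], [postProcess()]
#' @export
setClass("CellMapping", representation(pairs = "data.frame"))

setValidity("CellMapping", function(object) {
    p <- object@pairs
    if (!all(c("from", "to", "provenance") %in% names(p)))
        return("'pairs' needs columns from, to, provenance")
    if (anyDuplicated(p$from) || anyDuplicated(p$to))
        return("mapping must be injective in both directions")
    TRUE
})

#' @param from,to integer cell ids in the first and second frame.
#' @param provenance character vector, recycled; one of `"seed"`, `"mcs"`,
#'   `"post"`.
#' @return `cellMapping()` returns a `CellMapping`.
#' @rdname CellMapping-class
#' @export
cellMapping <- function(from = integer(), to = integer(),
                        provenance = character()) {
    if (length(from) && !length(provenance)) provenance <- "mcs"
    new("CellMapping", pairs = data.frame(
        from = as.integer(from), to = as.integer(to),
        provenance = rep_len(as.character(provenance),
                             length.out = length(from))))
}

#' @rdname epimcs-generics
#' @export
setMethod("mappingPairs", "CellMapping", function(x, ...) x@pairs)

setMethod("show", "CellMapping", function(object) {
    p <- object@pairs
    cat("CellMapping with", nrow(p), "pairs")
    if (nrow(p)) {
        tb <- table(p$provenance)
        cat(" (", paste(names(tb), tb, sep = ": ", collapse = ", "), ")",
            sep = "")
    }
    cat("\n")
})

setMethod("length", "CellMapping", function(x) nrow(x@pairs))

## ---------------------------------------------------------------------------
## TrackingResult
## ---------------------------------------------------------------------------

#' Result of tracking one frame pair
#'
#' Holds the final cell-to-cell mapping together with the resolved events:
#' divisions (mother in frame 1, two daughters in frame 2), deaths
#' (frame-1 cells that disappear in the interior of the tracked region) and
#' the remaining untracked cells of each frame. Division mothers are not in
#' the mapping's domain and daughters are not in its image.
#'
#' @slot mapping a [CellMapping-class]
#' @slot divisions data.frame with integer columns `mother`, `daughter1`,
#'   `daughter2`
#' @slot deaths integer vector of frame-1 cell ids
#' @slot untracked1,untracked2 integer vectors of cell ids that remain
#'   untracked in frames 1 and 2 (excluding deaths, mothers and daughters)
#' @slot notes character vector of warnings produced during event
#'   resolution (for example unresolved divisions)
#' @seealso [track()]
#' @export
setClass("TrackingResult",
    representation(mapping = "CellMapping", divisions = "data.frame",
                   deaths = "integer", untracked1 = "integer",
                   untracked2 = "integer", notes = "character"))

setValidity("TrackingResult", function(object) {
    p <- object@mapping@pairs
    d <- object@divisions
    msg <- character()
    if (!all(c("mother", "daughter1", "daughter2") %in% names(d)))
        msg <- c(msg, "'divisions' needs columns mother, daughter1, daughter2")
    else {
        if (any(d$mother %in% p$from))
            msg <- c(msg, "a division mother is still in the mapping domain")
        if (any(c(d$daughter1, d$daughter2) %in% p$to))
            msg <- c(msg, "a division daughter is in the mapping image")
    }
    if (any(object@deaths %in% p$from))
        msg <- c(msg, "a death is in the mapping domain")
    if (length(msg)) msg else TRUE
})

.trackingResult <- function(mapping, divisions = NULL, deaths = integer(),
                            untracked1 = integer(), untracked2 = integer(),
                            notes = character()) {
    if (is.null(divisions))
        divisions <- data.frame(mother = integer(), daughter1 = integer(),
                                daughter2 = integer())
    new("TrackingResult", mapping = mapping, divisions = divisions,
        deaths = as.integer(deaths), untracked1 = as.integer(untracked1),
        untracked2 = as.integer(untracked2), notes = notes)
}

#' @rdname epimcs-generics
#' @export
setMethod("trackedMapping", "TrackingResult", function(x, ...) x@mapping)

#' @rdname epimcs-generics
#' @export
setMethod("mappingPairs", "TrackingResult",
          function(x, ...) x@mapping@pairs)

#' @rdname epimcs-generics
#' @export
setMethod("divisions", "TrackingResult", function(x, ...) x@divisions)

#' @rdname epimcs-generics
#' @export
setMethod("deaths", "TrackingResult", function(x, ...) x@deaths)

#' @rdname epimcs-generics
#' @param frame for `untrackedCells()`, which frame (1 or 2) to report.
#' @export
setMethod("untrackedCells", "TrackingResult", function(x, frame = 1L, ...) {
    if (frame == 1L) x@untracked1 else x@untracked2
})

setMethod("show", "TrackingResult", function(object) {
    cat("TrackingResult:", nrow(object@mapping@pairs), "tracked pairs,",
        nrow(object@divisions), "divisions,",
        length(object@deaths), "deaths\n")
    cat("  untracked:", length(object@untracked1), "in frame 1,",
        length(object@untracked2), "in frame 2\n")
    if (length(object@notes))
        cat("  notes:", paste(object@notes, collapse = "; "), "\n")
})

## ---------------------------------------------------------------------------
## GroundTruth
## ---------------------------------------------------------------------------

#' Known correspondence for a synthetic test case
#'
#' Records the true cell-to-cell map between two synthetic frames, plus any
#' division and removal events applied when the second frame was generated.
#' Used by [scoreAgainstTruth()] to classify tracked pairs as correct,
#' incorrect or untracked.
#'
#' @slot map data.frame with integer columns `from`, `to`
#' @slot divisions data.frame with integer columns `mother`, `daughter1`,
#'   `daughter2` (ids in the respective frames)
#' @slot removed integer vector of frame-1 cells removed (T2 transitions)
#' @export
setClass("GroundTruth",
    representation(map = "data.frame", divisions = "data.frame",
                   removed = "integer"))

setValidity("GroundTruth", function(object) {
    m <- object@map
    if (!all(c("from", "to") %in% names(m)))
        return("'map' needs columns from, to")
    if (anyDuplicated(m$from) || anyDuplicated(m$to))
        return("ground-truth map must be injective")
    if (any(object@removed %in% m$from))
        return("removed cells cannot appear in the map domain")
    TRUE
})

#' @param from,to integer id vectors defining the true map.
#' @param divisions,removed optional event records, see slots.
#' @return `groundTruth()` returns a `GroundTruth`.
#' @rdname GroundTruth-class
#' @export
groundTruth <- function(from = integer(), to = integer(), divisions = NULL,
                        removed = integer()) {
    if (is.null(divisions))
        divisions <- data.frame(mother = integer(), daughter1 = integer(),
                                daughter2 = integer())
    new("GroundTruth",
        map = data.frame(from = as.integer(from), to = as.integer(to)),
        divisions = divisions, removed = as.integer(removed))
}

#' @rdname epimcs-generics
#' @export
setMethod("truthMap", "GroundTruth", function(x, ...) x@map)

setMethod("show", "GroundTruth", function(object) {
    cat("GroundTruth:", nrow(object@map), "mapped cells,",
        nrow(object@divisions), "divisions,",
        length(object@removed), "removals\n")
})
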