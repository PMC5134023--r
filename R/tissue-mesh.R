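#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## internal edge bookkeeping
## ---------------------------------------------------------------------------

## one row per directed polygon edge: owning cell, vertex pair (va < vb) and
## a collapsed string key used for grouping shared edges
.meshEdgeTable <- function(mesh) {
    cl <- mesh@cells
    if (!length(cl))
        return(data.frame(cell = integer(), va = integer(), vb = integer(),
                          key = character()))
    nv <- lengths(cl)
    cell <- rep(as.integer(names(cl)), nv)
    v1 <- unlist(cl, use.names = FALSE)
    v2 <- unlist(lapply(cl, function(ids) c(ids[-1L], ids[1L])),
                 use.names = FALSE)
    va <- pmin(v1, v2)
    vb <- pmax(v1, v2)
    data.frame(cell = cell, va = va, vb = vb,
               key = paste(va, vb, sep = "_"))
}

## unique undirected mesh edges with the one or two cells on either side
.sharedEdges <- function(mesh) {
    ed <- .meshEdgeTable(mesh)
    if (!nrow(ed))
        return(data.frame(va = integer(), vb = integer(),
                          cell1 = integer(), cell2 = integer()))
    o <- order(ed$key)
    ed <- ed[o, ]
    first <- !duplicated(ed$key)
    idx1 <- which(first)
    idx2 <- c(idx1[-1L] - 1L, nrow(ed))
    cnt <- idx2 - idx1 + 1L
    if (any(cnt > 2L))
        stop("invalid mesh: an edge is shared by more than two cells")
    data.frame(va = ed$va[idx1], vb = ed$vb[idx1],
               cell1 = ed$cell[idx1],
               cell2 = ifelse(cnt == 2L, ed$cell[idx2], NA_integer_))
}

## ---------------------------------------------------------------------------
## accessors
## ---------------------------------------------------------------------------

#' @rdname epimcs-generics
#' @export
setMethod("cellIds", "CellMesh",
          function(x, ...) as.integer(names(x@cells)))

#' @rdname epimcs-generics
#' @export
setMethod("nCells", "CellMesh", function(x, ...) length(x@cells))

#' @rdname epimcs-generics
#' @export
setMethod("vertexCoords", "CellMesh", function(x, ...) x@vertices)

#' @rdname epimcs-generics
#' @export
setMethod("cellPolygons", "CellMesh", function(x, ...) x@cells)

#' @rdname epimcs-generics
#' @export
setMethod("cellCentroids", "CellMesh", function(x, ...) {
    v <- x@vertices
    out <- t(vapply(x@cells, function(ids)
        .polygonCentroid(v[as.character(ids), , drop = FALSE]),
        numeric(2)))
    colnames(out) <- c("x", "y")
    out
})

#' @rdname epimcs-generics
#' @export
setMethod("cellAreas", "CellMesh", function(x, ...) {
    v <- x@vertices
    vapply(x@cells, function(ids)
        .polygonArea(v[as.character(ids), , drop = FALSE]), numeric(1))
})

#' @describeIn epimcs-generics mean cell length of a mesh, defined as the
#'   square root of the mean cell area. This is the length unit in which the
#'   tracker's displacement cutoff `dMax` is expressed.
#' @export
setMethod("meanCellLength", "CellMesh",
          function(x, ...) sqrt(mean(cellAreas(x))))

#' @describeIn epimcs-generics ids of cells owning at least one polygon edge
#'   that is not shared with another cell (the tissue boundary).
#' @export
setMethod("boundaryCells", "CellMesh", function(x, ...) {
    se <- .sharedEdges(x)
    sort(unique(se$cell1[is.na(se$cell2)]))
})

## ---------------------------------------------------------------------------
## dual network
## ---------------------------------------------------------------------------

#' Build the dual cell-adjacency network of a mesh
#'
#' Every cell becomes a network vertex (named by its integer cell id); two
#' vertices are connected if the corresponding polygons share at least one
#' edge. Multiple shared polygon edges collapse to a single network edge.
#' The degree of an interior cell therefore equals its number of polygon
#' sides.
#'
#' @param x a [CellMesh-class]
#' @param ... ignored
#' @return an [igraph::igraph] graph whose vertex names are the cell ids
#' @examples
#' mesh <- hexagonalMesh(3, 3)
#' net <- cellNetwork(mesh)
#' igraph::degree(net)
#' @export
setMethod("cellNetwork", "CellMesh", function(x, ...) {
    se <- .sharedEdges(x)
    shared <- se[!is.na(se$cell2), c("cell1", "cell2")]
    shared <- unique(shared[order(shared$cell1, shared$cell2), ])
    ids <- sort(as.integer(names(x@cells)))
    g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = as.character(ids))
    if (nrow(shared)) {
        ep <- rbind(match(shared$cell1, ids), match(shared$cell2, ids))
        g <- igraph::add_edges(g, as.vector(ep))
    }
    g
})

#' Local neighbourhood graph around a cell
#'
#' Returns the subgraph induced by a cell together with its neighbours
#' (`order = 1`) or its neighbours and second-nearest neighbours
#' (`order = 2`). The centre cell is marked with a logical vertex attribute
#' `centre`. This is the neighbourhood used both when seeding the maximum
#' common subgraph and when scoring candidate matches during its extension.
#'
#' @param net an igraph network as returned by [cellNetwork()]
#' @param cell integer cell id present in `net`
#' @param order neighbourhood order, 1 or 2
#' @return an igraph graph with vertex attribute `centre`
#' @export
neighbourhoodGraph <- function(net, cell, order = 2) {
    vn <- igraph::V(net)$name
    i <- match(as.character(cell), vn)
    if (is.na(i)) stop("unknown cell id: ", cell)
    keep <- unlist(igraph::ego(net, order = order, nodes = i))
    sub <- igraph::induced_subgraph(net, sort(unique(as.integer(keep))))
    igraph::set_vertex_attr(sub, "centre",
                            value = igraph::V(sub)$name == as.character(cell))
}

## ---------------------------------------------------------------------------
## serialization
## ---------------------------------------------------------------------------

#' Read and write meshes as JSON frame files
#'
#' The interchange format is a small JSON document with a `vertices` array
#' (`id`, `x`, `y`) and a `cells` array (`id`, ordered `vertices` id list).
#' Round trips are lossless up to double precision.
#'
#' @param mesh a [CellMesh-class]
#' @param path file path
#' @return `readCellMesh()` returns a `CellMesh`; `writeCellMesh()` returns
#'   `path` invisibly.
#' @export
writeCellMesh <- function(mesh, path) {
    v <- mesh@vertices
    doc <- list(
        vertices = data.frame(id = as.integer(rownames(v)),
                              x = v[, 1], y = v[, 2]),
        cells = lapply(seq_along(mesh@cells), function(i) list(
            id = as.integer(names(mesh@cells)[i]),
            vertices = mesh@cells[[i]])))
    jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
    invisible(path)
}

#' @rdname writeCellMesh
#' @export
readCellMesh <- function(path) {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                               simplifyDataFrame = TRUE)
    cells <- lapply(doc$cells$vertices, as.integer)
    names(cells) <- as.character(doc$cells$id)
    cellMesh(doc$vertices, cells)
}

## ---------------------------------------------------------------------------
## plotting
## ---------------------------------------------------------------------------

#' Plot a cell mesh
#'
#' Draws the polygonal tessellation with base graphics. Cells can be
#' coloured, e.g. by tracking provenance.
#'
#' @param x a [CellMesh-class]
#' @param col fill colours, recycled over cells (in `cellIds()` order)
#' @param labels logical; draw cell ids at the centroids
#' @param add logical; add to an existing plot
#' @param ... passed to [graphics::plot.default()]
#' @return invisibly, `x`
#' @export
plotMesh <- function(x, col = NA, labels = FALSE, add = FALSE, ...) {
    v <- x@vertices
    if (!add)
        graphics::plot(v[, 1], v[, 2], type = "n", asp = 1,
                       xlab = "x", ylab = "y", ...)
    col <- rep_len(col, length(x@cells))
    for (i in seq_along(x@cells)) {
        p <- v[as.character(x@cells[[i]]), , drop = FALSE]
        graphics::polygon(p[, 1], p[, 2], col = col[i], border = "grey25")
    }
    if (labels) {
        ce <- cellCentroids(x)
        graphics::text(ce[, 1], ce[, 2], names(x@cells), cex = 0.6)
    }
    invisible(x)
}
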