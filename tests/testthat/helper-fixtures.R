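## Fixtures built in code: small meshes with known structure.

## nx x ny grid of unit squares (4-fold junctions are ordinary vertices)
rectangularMesh <- function(nx, ny) {
    vid <- function(i, j) (j - 1L) * (nx + 1L) + i
    vs <- expand.grid(i = seq_len(nx + 1L), j = seq_len(ny + 1L))
    verts <- cbind(x = vs$i - 1, y = vs$j - 1)
    rownames(verts) <- seq_len(nrow(verts))
    cells <- list()
    k <- 0L
    for (j in seq_len(ny)) {
        for (i in seq_len(nx)) {
            k <- k + 1L
            cells[[as.character(k)]] <-
                c(vid(i, j), vid(i + 1L, j), vid(i + 1L, j + 1L),
                  vid(i, j + 1L))
        }
    }
    cellMesh(verts, cells)
}

## brute-force adjacency oracle: all cell pairs sharing a polygon edge
bruteForceAdjacency <- function(mesh) {
    cells <- cellPolygons(mesh)
    ids <- as.integer(names(cells))
    edgeSet <- lapply(cells, function(v) {
        w <- c(v[-1L], v[1L])
        paste(pmin(v, w), pmax(v, w))
    })
    out <- NULL
    for (a in seq_along(ids)) {
        for (b in seq_along(ids)) {
            if (b <= a) next
            if (length(intersect(edgeSet[[a]], edgeSet[[b]])))
                out <- rbind(out, c(ids[a], ids[b]))
        }
    }
    out[order(out[, 1], out[, 2]), , drop = FALSE]
}

edgesOfGraph <- function(g) {
    e <- igraph::as_edgelist(g)
    e <- cbind(as.integer(e[, 1]), as.integer(e[, 2]))
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    e[order(e[, 1], e[, 2]), , drop = FALSE]
}

## neighbour id sets keyed by cell id
neighbourSets <- function(mesh) {
    g <- cellNetwork(mesh)
    vn <- igraph::V(g)$name
    sets <- lapply(seq_along(vn), function(i)
        sort(as.integer(vn[as.integer(igraph::neighbors(g, i))])))
    names(sets) <- vn
    sets
}

## Division test case whose cut snaps onto an existing junction vertex,
## producing a reduced-side daughter (the network-ambiguous situation that
## must be resolved geometrically). Returns NULL when seed s does not
## produce a snapped case.
.withSnapCase <- function(s) {
    set.seed(3000 + s)
    mesh <- generateTissue(9, 9)
    ids <- cellIds(mesh)
    interior <- setdiff(ids, boundaryCells(mesh))
    ce <- cellCentroids(mesh)
    victim <- interior[which.min((ce[match(interior, ids), 1] - 4.5)^2 +
                                 (ce[match(interior, ids), 2] - 4.5)^2)]
    poly <- vertexCoords(mesh)[as.character(
        cellPolygons(mesh)[[as.character(victim)]]), , drop = FALSE]
    cent <- epimcs:::.polygonCentroid(poly)
    ang <- atan2(poly[1, 2] - cent[2], poly[1, 1] - cent[1])
    dv <- tryCatch(applyDivision(mesh, victim, angle = ang),
                   notApplicableError = function(e) NULL,
                   error = function(e) NULL)
    if (is.null(dv)) return(NULL)
    ns <- lengths(cellPolygons(dv$mesh)[as.character(
        c(dv$record$daughter1, dv$record$daughter2))])
    if (!any(ns <= 4)) return(NULL)
    pm <- permuteIds(dv$mesh)
    tm <- truthMap(pm$truth)
    relab <- function(id) tm$to[match(id, tm$from)]
    dd <- sort(c(relab(dv$record$daughter1), relab(dv$record$daughter2)))
    keep <- !tm$from %in% c(dv$record$daughter1, dv$record$daughter2)
    list(mesh1 = mesh, mesh2 = pm$mesh,
         truth = groundTruth(tm$from[keep], tm$to[keep],
                             divisions = data.frame(
                                 mother = dv$record$mother,
                                 daughter1 = dd[1], daughter2 = dd[2])))
}

## brute-force maximum common connected induced subgraph size, anchored at
## given vertices of two igraphs; pure enumeration over vertex subsets
bruteForceMCSSize <- function(g1, g2, a1, a2) {
    n1 <- igraph::vcount(g1)
    n2 <- igraph::vcount(g2)
    A1 <- igraph::as_adjacency_matrix(g1, sparse = FALSE)
    A2 <- igraph::as_adjacency_matrix(g2, sparse = FALSE)
    best <- 0L
    recurse <- function(map1, map2, size) {
        if (size > best) best <<- size
        for (u in seq_len(n1)) {
            if (map1[u] != 0L) next
            if (!any(map1 != 0L & A1[u, ] == 1)) next
            for (v in seq_len(n2)) {
                if (map2[v] != 0L) next
                ok <- TRUE
                conn <- FALSE
                for (a in seq_len(n1)) {
                    if (map1[a] == 0L) next
                    if (A1[u, a] != A2[v, map1[a]]) { ok <- FALSE; break }
                    if (A1[u, a] == 1) conn <- TRUE
                }
                if (!ok || !conn) next
                map1[u] <- v; map2[v] <- u
                recurse(map1, map2, size + 1L)
                map1[u] <- 0L; map2[v] <- 0L
            }
        }
    }
    map1 <- integer(n1); map2 <- integer(n2)
    map1[a1] <- a2; map2[a2] <- a1
    recurse(map1, map2, 1L)
    best
}
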