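#' @include tissue-mesh.R
NULL

## run expr with a temporarily seeded RNG, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}

## ---------------------------------------------------------------------------
## Voronoi / Lloyd generator
## ---------------------------------------------------------------------------

## two rows of evenly spaced guard seeds around the domain [0,W] x [0,H]:
## the inner row at distance 0.5 with spacing 1.0, the outer row at
## distance 1.5, shifted along the boundary by 0.5
.guardSeeds <- function(W, H) {
    xi <- seq(-1, W + 1, by = 1)
    xo <- seq(-1.5, W + 1.5, by = 1)
    yi <- seq(0.5, H - 0.5, by = 1)
    yo <- seq(0, H, by = 1)
    rbind(cbind(xi, -0.5), cbind(xi, H + 0.5),
          cbind(-0.5, yi), cbind(W + 0.5, yi),
          cbind(xo, -1.5), cbind(xo, H + 1.5),
          cbind(-1.5, yo), cbind(W + 1.5, yo))
}

.voronoiDiagram <- function(seeds, W, H) {
    deldir::deldir(seeds[, 1], seeds[, 2],
                   rw = c(-2.5, W + 2.5, -2.5, H + 2.5),
                   suppressMsge = TRUE)
}

.voronoiTiles <- function(d, which) {
    tl <- deldir::tile.list(d)
    ## index tiles by original point number (deldir keeps input order when
    ## there are no duplicated points)
    tl[order(vapply(tl, function(t) t$ptNum, numeric(1)))][which]
}

## area centroids of the first k (interior) Dirichlet tiles, computed from
## the segment table by fanning triangles around each seed; tiles of
## interior seeds are convex and unclipped, so the fan tiles them exactly
.tileCentroids <- function(d, seeds, k) {
    sg <- d$dirsgs
    ind <- c(sg$ind1, sg$ind2)
    x1 <- rep(sg$x1, 2); y1 <- rep(sg$y1, 2)
    x2 <- rep(sg$x2, 2); y2 <- rep(sg$y2, 2)
    keep <- ind <= k
    ind <- ind[keep]
    sx <- seeds[ind, 1]; sy <- seeds[ind, 2]
    x1 <- x1[keep]; y1 <- y1[keep]; x2 <- x2[keep]; y2 <- y2[keep]
    a <- abs((x1 - sx) * (y2 - sy) - (x2 - sx) * (y1 - sy)) / 2
    agg <- rowsum(cbind(a, a * (sx + x1 + x2) / 3, a * (sy + y1 + y2) / 3),
                  ind)
    out <- matrix(NA_real_, k, 2)
    out[as.integer(rownames(agg)), ] <- agg[, 2:3] / agg[, 1]
    out
}

#' Generate an in-silico epithelial tissue
#'
#' Produces a polygonal tessellation that emulates cell packings observed
#' in epithelia: `(m + g) x (n + g)` random Voronoi seeds are placed in a
#' padded domain surrounded by two rows of evenly spaced guard seeds (so no
#' interior region is unbounded), the tessellation is homogenised with
#' `nLloyd` steps of Lloyd's relaxation (each step replaces the interior
#' seeds by the centroids of their polygons and re-adds the guard rows),
#' and finally only the polygons whose centroids lie in the central
#' `m x n` rectangle are kept. The result has approximately `m * n` cells
#' of average area 1, with coordinates shifted so that the central
#' rectangle is `[0, m] x [0, n]`.
#'
#' @param m,n tissue dimensions in cells (at least 3)
#' @param g width of the padded boundary region, in cell lengths
#' @param nLloyd number of Lloyd's relaxation steps
#' @param seed optional integer; when given, the generator is run with a
#'   private RNG stream seeded with this value and is bit-reproducible
#' @return a [CellMesh-class] with cell ids `1, 2, ...` in seed order
#' @examples
#' mesh <- generateTissue(9, 9, seed = 1)
#' nCells(mesh)
#' mean(cellAreas(mesh))
#' @export
generateTissue <- function(m, n, g = 8, nLloyd = 4, seed = NULL) {
    stopifnot(m >= 3, n >= 3, g >= 0, nLloyd >= 0)
    .withSeed(seed, {
        W <- m + g
        H <- n + g
        k <- (m + g) * (n + g)
        pts <- cbind(stats::runif(k, 0, W), stats::runif(k, 0, H))
        while (anyDuplicated(round(pts, 12))) # guard against coincident seeds
            pts <- cbind(stats::runif(k, 0, W), stats::runif(k, 0, H))
        guards <- .guardSeeds(W, H)
        for (step in seq_len(nLloyd)) {
            all <- rbind(pts, guards)
            d <- .voronoiDiagram(all, W, H)
            pts <- .tileCentroids(d, all, k)
        }
        d <- .voronoiDiagram(rbind(pts, guards), W, H)
        tl <- .voronoiTiles(d, seq_len(k))
        .meshFromTiles(tl, W, H, m, n)
    })
}

## assemble a CellMesh from deldir tiles, keeping polygons whose centroids
## fall in the central m x n rectangle; shared Voronoi vertices coincide
## bitwise across tiles, so topology is exact
.meshFromTiles <- function(tl, W, H, m, n) {
    x0 <- (W - m) / 2
    y0 <- (H - n) / 2
    keep <- vapply(tl, function(t) {
        ce <- .polygonCentroid(cbind(t$x, t$y))
        ce[1] >= x0 && ce[1] <= x0 + m && ce[2] >= y0 && ce[2] <= y0 + n
    }, logical(1))
    tl <- tl[keep]
    if (length(tl) < 3L) stop("degenerate tissue: fewer than 3 cells")
    pts <- lapply(tl, function(t) {
        px <- t$x
        py <- t$y
        ## drop consecutive duplicated points, if any
        dup <- c(FALSE, px[-1] == px[-length(px)] & py[-1] == py[-length(py)])
        cbind(px[!dup], py[!dup])
    })
    all <- do.call(rbind, pts)
    keys <- paste(sprintf("%.14g", all[, 1]), sprintf("%.14g", all[, 2]))
    uk <- !duplicated(keys)
    idx <- match(keys, keys[uk])
    cells <- split(idx, rep(seq_along(pts), vapply(pts, nrow, integer(1))))
    names(cells) <- seq_along(cells)
    vm <- cbind(x = all[uk, 1] - x0, y = all[uk, 2] - y0)
    rownames(vm) <- seq_len(nrow(vm))
    cellMesh(vm, cells)
}

## ---------------------------------------------------------------------------
## perturbation operators
## ---------------------------------------------------------------------------

#' Randomly permute the cell identifiers of a mesh
#'
#' Geometry is untouched; only the integer cell ids are shuffled. The
#' returned ground truth records the old-to-new correspondence.
#'
#' @param mesh a [CellMesh-class]
#' @param seed optional integer seed for the shuffle
#' @return list with components `mesh` and `truth` (a [GroundTruth-class])
#' @export
permuteIds <- function(mesh, seed = NULL) {
    .withSeed(seed, {
        ids <- as.integer(names(mesh@cells))
        newIds <- sample(ids)
        cells <- mesh@cells
        names(cells) <- as.character(newIds)
        list(mesh = cellMesh(mesh@vertices, cells),
             truth = groundTruth(ids, newIds))
    })
}

#' Build the tissue-translation test pair
#'
#' From a single `15 x 8` tissue, two full-height windows of width 7 are
#' cut whose left edges are offset by two cell lengths; both are then
#' re-anchored so that their leftmost junction has x-coordinate 0.
#' Cutting clips cell polygons at the window planes (cells extending past
#' the field of view are kept with their visible part, as in a real
#' imaging window), so the adjacency structure inside the overlap is
#' preserved. The ground truth maps the cells whose (uncut) centroids
#' fall in both windows.
#'
#' @param seed optional integer seed for the underlying tissue
#' @param offset horizontal offset between the windows, in cell lengths
#' @param width window width in cell lengths
#' @param g,nLloyd generator parameters, see [generateTissue()]
#' @return list with components `mesh1`, `mesh2`, `truth`
#' @export
translationPair <- function(seed = NULL, offset = 2, width = 7,
                            g = 8, nLloyd = 4) {
    parent <- generateTissue(15, 8, g = g, nLloyd = nLloyd, seed = seed)
    mesh1 <- .clipWindow(parent, 0, width)
    mesh2 <- .clipWindow(parent, offset, offset + width)
    mesh1 <- .anchorLeft(mesh1)
    mesh2 <- .anchorLeft(mesh2)
    ce <- cellCentroids(parent)
    shared <- cellIds(parent)[ce[, 1] >= offset & ce[, 1] <= width]
    shared <- intersect(shared, intersect(cellIds(mesh1), cellIds(mesh2)))
    list(mesh1 = mesh1, mesh2 = mesh2,
         truth = groundTruth(shared, shared))
}

## clip a mesh to the vertical strip [x0, x1]; polygons are cut at the
## strip boundaries (crossing vertices are computed once per mesh edge, so
## adjacent cells share them exactly) and cells left with fewer than three
## vertices or without interior area are dropped
.clipWindow <- function(mesh, x0, x1) {
    out <- .clipHalfplane(mesh, x0, keepRight = TRUE)
    .clipHalfplane(out, x1, keepRight = FALSE)
}

.clipHalfplane <- function(mesh, xc, keepRight) {
    v <- mesh@vertices
    tol <- 1e-9
    inside <- if (keepRight) v[, 1] >= xc - tol else v[, 1] <= xc + tol
    names(inside) <- rownames(v)
    nextId <- max(as.integer(rownames(v)))
    crossId <- new.env(parent = emptyenv())
    newX <- numeric()
    newY <- numeric()
    newIds <- integer()
    getCross <- function(a, b) {
        key <- paste(min(a, b), max(a, b))
        hit <- crossId[[key]]
        if (!is.null(hit)) return(hit)
        p <- v[as.character(min(a, b)), ]
        q <- v[as.character(max(a, b)), ]
        t <- (xc - p[1]) / (q[1] - p[1])
        nextId <<- nextId + 1L
        newX <<- c(newX, xc)
        newY <<- c(newY, p[2] + t * (q[2] - p[2]))
        newIds <<- c(newIds, nextId)
        crossId[[key]] <- nextId
        nextId
    }
    cells <- lapply(mesh@cells, function(ids) {
        n <- length(ids)
        outIds <- integer()
        for (i in seq_len(n)) {
            a <- ids[i]
            b <- ids[if (i == n) 1L else i + 1L]
            ia <- inside[as.character(a)]
            ib <- inside[as.character(b)]
            if (ia) outIds <- c(outIds, a)
            if (ia != ib) outIds <- c(outIds, getCross(a, b))
        }
        outIds <- outIds[outIds != c(outIds[-1L], outIds[1L])]
        outIds
    })
    keep <- lengths(cells) >= 3L
    cells <- cells[keep]
    vm <- rbind(v, cbind(x = newX, y = newY))
    rownames(vm) <- c(rownames(v), as.character(newIds))
    ## drop degenerate (zero-area) clipped slivers
    areas <- vapply(cells, function(ids)
        .polygonArea(vm[as.character(ids), , drop = FALSE]), numeric(1))
    cells <- cells[areas > 1e-9]
    used <- as.character(sort(unique(unlist(cells))))
    cellMesh(vm[used, , drop = FALSE], cells)
}

.subMesh <- function(mesh, ids) {
    cells <- mesh@cells[as.character(ids)]
    used <- as.character(sort(unique(unlist(cells))))
    cellMesh(mesh@vertices[used, , drop = FALSE], cells)
}

.anchorLeft <- function(mesh) {
    v <- mesh@vertices
    v[, 1] <- v[, 1] - min(v[, 1])
    cellMesh(v, mesh@cells)
}

#' Edges eligible for a T1 transition
#'
#' An inner edge is a polygon edge shared by two cells whose endpoints are
#' both three-cell junctions (each vertex belongs to exactly three cells
#' and not to the tissue boundary). To keep the neighbour-exchange
#' bookkeeping exact, edges whose flanking junction cells are already
#' adjacent, or whose two cells share more than one edge, are excluded.
#'
#' @param mesh a [CellMesh-class]
#' @return data.frame with columns `va`, `vb` (vertex ids), `cellP`,
#'   `cellQ` (the cells losing adjacency) and `cellA`, `cellB` (the cells
#'   gaining adjacency)
#' @export
innerEdges <- function(mesh) {
    se <- .sharedEdges(mesh)
    ed <- .meshEdgeTable(mesh)
    ## cells at each vertex
    vcells <- split(rep(as.integer(names(mesh@cells)),
                        lengths(mesh@cells)),
                    unlist(mesh@cells, use.names = FALSE))
    vcells <- lapply(vcells, unique)
    nAt <- lengths(vcells)
    ## vertices on the tissue boundary (endpoint of an unshared edge)
    bverts <- unique(c(se$va[is.na(se$cell2)], se$vb[is.na(se$cell2)]))
    se <- se[!is.na(se$cell2), , drop = FALSE]
    ## shared-edge multiplicity per cell pair
    pk <- paste(pmin(se$cell1, se$cell2), pmax(se$cell1, se$cell2))
    multi <- pk %in% pk[duplicated(pk)]
    adjKey <- unique(pk)
    ok <- !multi & !(se$va %in% bverts) & !(se$vb %in% bverts) &
        nAt[as.character(se$va)] == 3L & nAt[as.character(se$vb)] == 3L
    idx <- which(ok)
    keep <- logical(length(idx))
    A <- B <- integer(length(idx))
    for (k in seq_along(idx)) {
        i <- idx[k]
        a <- setdiff(vcells[[as.character(se$va[i])]],
                     c(se$cell1[i], se$cell2[i]))
        b <- setdiff(vcells[[as.character(se$vb[i])]],
                     c(se$cell1[i], se$cell2[i]))
        if (length(a) != 1L || length(b) != 1L || a == b) next
        if (paste(min(a, b), max(a, b)) %in% adjKey) next
        keep[k] <- TRUE
        A[k] <- a
        B[k] <- b
    }
    idx <- idx[keep]
    data.frame(va = se$va[idx], vb = se$vb[idx], cellP = se$cell1[idx],
               cellQ = se$cell2[idx], cellA = A[keep], cellB = B[keep])
}

## replace, in cell's vertex cycle, the consecutive pair (a, b) (in either
## cyclic order) by the given replacement vertices
.replaceEdgeInCell <- function(ids, a, b, repl) {
    n <- length(ids)
    for (i in seq_len(n)) {
        j <- if (i == n) 1L else i + 1L
        if ((ids[i] == a && ids[j] == b) || (ids[i] == b && ids[j] == a)) {
            rest <- if (j > i) ids[-c(i, j)] else ids[-c(1L, n)]
            pos <- if (j > i) i - 1L else n - 2L
            return(append(rest, repl, after = pos))
        }
    }
    stop("edge not found in cell")
}

.replaceVertexInCell <- function(ids, v, repl) {
    i <- match(v, ids)
    if (is.na(i)) stop("vertex not found in cell")
    append(ids[-i], repl, after = i - 1L)
}

.notApplicable <- function(msg) {
    structure(class = c("notApplicableError", "error", "condition"),
              list(message = msg, call = sys.call(-1)))
}

#' Apply a T1 transition (neighbour exchange) to a mesh edge
#'
#' The shared edge between cells P and Q collapses and is replaced by a new
#' edge of length `l` perpendicular to it through its midpoint. P and Q
#' lose their adjacency; the two cells flanking the old edge's junctions
#' gain one. Exactly four cells change their neighbour count.
#'
#' @param mesh a [CellMesh-class]
#' @param edge integer vector `c(va, vb)` of the edge's vertex ids; must be
#'   one of the rows of [innerEdges()]
#' @param l length of the new edge, in length units
#' @param edgeInfo optional precomputed row of [innerEdges()] for `edge`,
#'   to avoid re-deriving the applicable-edge table
#' @return the perturbed [CellMesh-class]
#' @export
applyT1 <- function(mesh, edge, l = 0.2, edgeInfo = NULL) {
    if (is.null(edgeInfo)) {
        ie <- innerEdges(mesh)
        hit <- which((ie$va == edge[1] & ie$vb == edge[2]) |
                     (ie$va == edge[2] & ie$vb == edge[1]))
        if (!length(hit))
            stop(.notApplicable("edge is not an applicable inner edge"))
        e <- ie[hit[1L], ]
    } else e <- edgeInfo
    v <- mesh@vertices
    a <- v[as.character(e$va), ]
    b <- v[as.character(e$vb), ]
    mid <- (a + b) / 2
    dir <- (b - a) / sqrt(sum((b - a)^2))
    perp <- c(-dir[2], dir[1])
    newId <- max(as.integer(rownames(v))) + 1:2
    pu <- mid + (l / 2) * perp
    pw <- mid - (l / 2) * perp
    cent <- function(cell) .polygonCentroid(
        v[as.character(mesh@cells[[as.character(cell)]]), , drop = FALSE])
    ## the endpoint on P's side of the new edge goes to P
    sP <- sum((cent(e$cellP) - mid) * perp)
    pVert <- if (sP > 0) newId[1L] else newId[2L]
    qVert <- if (sP > 0) newId[2L] else newId[1L]
    cells <- mesh@cells
    cells[[as.character(e$cellP)]] <-
        .replaceEdgeInCell(cells[[as.character(e$cellP)]], e$va, e$vb, pVert)
    cells[[as.character(e$cellQ)]] <-
        .replaceEdgeInCell(cells[[as.character(e$cellQ)]], e$va, e$vb, qVert)
    vm <- rbind(v, pu, pw)
    rownames(vm) <- c(rownames(v), as.character(newId))
    ## insert the full new edge into the flanking cells, trying both
    ## insertion orders and keeping the simple (larger-area) polygon
    insertBoth <- function(ids, old) {
        c1 <- .replaceVertexInCell(ids, old, newId)
        c2 <- .replaceVertexInCell(ids, old, rev(newId))
        a1 <- .polygonArea(vm[as.character(c1), , drop = FALSE])
        a2 <- .polygonArea(vm[as.character(c2), , drop = FALSE])
        if (a1 >= a2) c1 else c2
    }
    cells[[as.character(e$cellA)]] <-
        insertBoth(cells[[as.character(e$cellA)]], e$va)
    cells[[as.character(e$cellB)]] <-
        insertBoth(cells[[as.character(e$cellB)]], e$vb)
    used <- as.character(sort(unique(unlist(cells))))
    cellMesh(vm[used, , drop = FALSE], cells)
}

#' Apply a T2 transition (cell removal) to a mesh
#'
#' Removes an interior cell and replaces it by a single vertex at its
#' centroid, shared by all former neighbours; consecutive neighbours around
#' the removed cell keep their mutual edges, now meeting in a rosette at
#' the new vertex.
#'
#' @param mesh a [CellMesh-class]
#' @param cell id of an interior cell
#' @return the perturbed [CellMesh-class]
#' @export
applyT2 <- function(mesh, cell) {
    key <- as.character(cell)
    if (!key %in% names(mesh@cells)) stop("unknown cell id: ", cell)
    if (cell %in% boundaryCells(mesh))
        stop(.notApplicable("T2 requires an interior cell"))
    victim <- mesh@cells[[key]]
    v <- mesh@vertices
    ce <- .polygonCentroid(v[as.character(victim), , drop = FALSE])
    newId <- max(as.integer(rownames(v))) + 1L
    cells <- mesh@cells[names(mesh@cells) != key]
    cells <- lapply(cells, function(ids) {
        ids[ids %in% victim] <- newId
        ## collapse consecutive duplicates (cyclically)
        keep <- ids != c(ids[-1L], ids[1L])
        out <- ids[keep | ids != newId]
        out <- out[!(duplicated(out) & out == newId)]
        if (length(out) < 3L)
            stop(.notApplicable("T2 would degenerate a neighbouring cell"))
        out
    })
    vm <- rbind(v, ce)
    rownames(vm) <- c(rownames(v), as.character(newId))
    used <- as.character(sort(unique(unlist(cells))))
    cellMesh(vm[used, , drop = FALSE], cells)
}

#' Divide a cell along a straight line through its centroid
#'
#' The cell is bisected by a line in direction `angle` (drawn uniformly at
#' random when omitted) through its centroid. New vertices are inserted
#' where the line crosses the cell boundary — snapping to an existing
#' vertex when the crossing lands within `snapTol` of it, which is how
#' three- and four-sided daughters arise — and the two cells whose shared
#' edges are cut each gain one edge. The two daughters receive fresh ids.
#'
#' @param mesh a [CellMesh-class]
#' @param cell id of an interior cell
#' @param angle direction of the division line in radians; random if `NULL`
#' @param snapTol snapping tolerance for crossings near existing vertices
#' @return list with components `mesh` and `record` (a one-row data.frame
#'   `mother`, `daughter1`, `daughter2`)
#' @export
applyDivision <- function(mesh, cell, angle = NULL, snapTol = 1e-6) {
    key <- as.character(cell)
    if (!key %in% names(mesh@cells)) stop("unknown cell id: ", cell)
    if (cell %in% boundaryCells(mesh))
        stop(.notApplicable("division requires an interior cell"))
    if (is.null(angle)) angle <- stats::runif(1, 0, pi)
    v <- mesh@vertices
    ids <- mesh@cells[[key]]
    poly <- v[as.character(ids), , drop = FALSE]
    ce <- .polygonCentroid(poly)
    dir <- c(cos(angle), sin(angle))
    n <- length(ids)
    crossings <- NULL
    for (i in seq_len(n)) {
        j <- if (i == n) 1L else i + 1L
        t <- .segmentLineIntersection(poly[i, ], poly[j, ], ce, dir)
        if (is.na(t) || t < 0 || t >= 1) next
        pt <- poly[i, ] + t * (poly[j, ] - poly[i, ])
        crossings <- rbind(crossings, c(i, j, pt))
    }
    if (is.null(crossings) || nrow(crossings) != 2L)
        stop(.notApplicable("division line does not cross the boundary twice"))
    nextVid <- max(as.integer(rownames(v)))
    vm <- v
    cells <- mesh@cells
    cutVid <- integer(2)
    for (k in 1:2) {
        i <- crossings[k, 1L]
        pt <- crossings[k, 3:4]
        dpre <- sqrt(sum((pt - poly[i, ])^2))
        dpost <- sqrt(sum((pt - poly[crossings[k, 2L], ])^2))
        if (dpre < snapTol) {
            cutVid[k] <- ids[i]
        } else if (dpost < snapTol) {
            cutVid[k] <- ids[crossings[k, 2L]]
        } else {
            nextVid <- nextVid + 1L
            cutVid[k] <- nextVid
            vm <- rbind(vm, pt)
            rownames(vm)[nrow(vm)] <- as.character(nextVid)
            ## insert the new vertex into the neighbour sharing the cut edge
            a <- ids[i]; b <- ids[crossings[k, 2L]]
            for (other in names(cells)) {
                if (other == key) next
                oc <- cells[[other]]
                m <- length(oc)
                for (q in seq_len(m)) {
                    r <- if (q == m) 1L else q + 1L
                    if ((oc[q] == a && oc[r] == b) ||
                        (oc[q] == b && oc[r] == a)) {
                        cells[[other]] <- append(oc, nextVid, after = q)
                        break
                    }
                }
            }
        }
    }
    ## split the vertex cycle at the two crossings
    splitCycle <- function(ids, i1, j1, p1, i2, j2, p2) {
        ## walk from crossing 1 to crossing 2 and back
        seg1 <- integer()
        q <- j1
        repeat {
            seg1 <- c(seg1, ids[q])
            if (q == i2) break
            q <- if (q == length(ids)) 1L else q + 1L
        }
        seg2 <- integer()
        q <- j2
        repeat {
            seg2 <- c(seg2, ids[q])
            if (q == i1) break
            q <- if (q == length(ids)) 1L else q + 1L
        }
        d1 <- unique(c(p1, seg1, p2))
        d2 <- unique(c(p2, seg2, p1))
        list(d1, d2)
    }
    halves <- splitCycle(ids, crossings[1, 1], crossings[1, 2], cutVid[1],
                         crossings[2, 1], crossings[2, 2], cutVid[2])
    if (any(lengths(halves) < 3L))
        stop(.notApplicable("division would create a degenerate daughter"))
    dIds <- max(as.integer(names(cells))) + 1:2
    cells <- cells[names(cells) != key]
    cells[[as.character(dIds[1L])]] <- halves[[1L]]
    cells[[as.character(dIds[2L])]] <- halves[[2L]]
    used <- as.character(sort(unique(unlist(cells))))
    out <- cellMesh(vm[used, , drop = FALSE], cells)
    list(mesh = out,
         record = data.frame(mother = cell, daughter1 = dIds[1L],
                             daughter2 = dIds[2L]))
}

#' Apply T1 transitions to a random subset of a tissue's inner edges
#'
#' Draws edges without replacement from the applicable inner-edge pool of
#' the unperturbed tissue until `round(fraction * n)` transitions have been
#' applied, where `n` is the pool size. An edge made inapplicable by an
#' earlier transition (its junction vertices were consumed, or its flanking
#' cells have become adjacent) is rejected and another edge is drawn, so
#' transitions may touch overlapping cell sets just as independent
#' neighbour exchanges in a real tissue do.
#'
#' @param mesh a [CellMesh-class]
#' @param fraction fraction of inner edges to swap
#' @param l new-edge length, see [applyT1()]
#' @return list with components `mesh`, `nApplied` and `nInner` (the size
#'   of the original applicable-edge pool)
#' @export
applyRandomT1s <- function(mesh, fraction, l = 0.2) {
    ie <- innerEdges(mesh)
    nInner <- nrow(ie)
    target <- round(fraction * nInner)
    applied <- 0L
    deadVerts <- integer()   # junction vertices consumed by earlier T1s
    newAdj <- character()    # cell pairs made adjacent by earlier T1s
    while (applied < target && nrow(ie)) {
        k <- if (nrow(ie) == 1L) 1L else sample.int(nrow(ie), 1L)
        e <- ie[k, ]
        ie <- ie[-k, , drop = FALSE]
        if (e$va %in% deadVerts || e$vb %in% deadVerts) next
        if (paste(min(e$cellA, e$cellB), max(e$cellA, e$cellB)) %in% newAdj)
            next
        mesh <- applyT1(mesh, c(e$va, e$vb), l = l, edgeInfo = e)
        applied <- applied + 1L
        deadVerts <- c(deadVerts, e$va, e$vb)
        newAdj <- c(newAdj,
                    paste(min(e$cellA, e$cellB), max(e$cellA, e$cellB)))
    }
    list(mesh = mesh, nApplied = applied, nInner = nInner)
}

## ---------------------------------------------------------------------------
## regular lattice (fixture and homogeneity reference)
## ---------------------------------------------------------------------------

#' Regular hexagonal lattice mesh
#'
#' A perfectly homogeneous packing of `nx` by `ny` regular hexagons,
#' useful as a reference tissue (every interior cell has six neighbours)
#' and as a worst case for purely network-based tracking.
#'
#' @param nx,ny lattice dimensions in cells
#' @param side hexagon side length
#' @return a [CellMesh-class]
#' @export
hexagonalMesh <- function(nx, ny, side = 1) {
    s <- side
    w <- sqrt(3) * s
    vkey <- character()
    vx <- numeric()
    vy <- numeric()
    cells <- vector("list", nx * ny)
    ang <- pi / 6 + (0:5) * pi / 3
    k <- 0L
    for (row in seq_len(ny)) {
        for (col in seq_len(nx)) {
            cx <- (col - 1) * w + if (row %% 2 == 0) w / 2 else 0
            cy <- (row - 1) * 1.5 * s
            px <- cx + s * cos(ang)
            py <- cy + s * sin(ang)
            keys <- paste(round(px, 9), round(py, 9))
            idx <- match(keys, vkey)
            miss <- which(is.na(idx))
            if (length(miss)) {
                vkey <- c(vkey, keys[miss])
                vx <- c(vx, px[miss])
                vy <- c(vy, py[miss])
                idx <- match(keys, vkey)
            }
            k <- k + 1L
            cells[[k]] <- idx
        }
    }
    names(cells) <- seq_len(k)
    vm <- cbind(x = vx, y = vy)
    rownames(vm) <- seq_along(vx)
    cellMesh(vm, cells)
}

## ---------------------------------------------------------------------------
## canonical test cases
## ---------------------------------------------------------------------------

#' Build a synthetic tracking test case with ground truth
#'
#' Constructs the five canonical frame-pair test cases used to validate
#' the tracker: `"permutation"` (identical geometry, shuffled ids),
#' `"translation"` (two windows of a wider tissue offset by two cell
#' lengths), `"t1"` (one neighbour exchange on a central edge), `"t2"`
#' (removal of the central cell) and `"division"` (bisection of a central
#' cell at a random orientation). In every case the second frame's ids are
#' randomly shuffled and the ground truth records the true correspondence
#' plus any division/removal event.
#'
#' @param type one of `"permutation"`, `"translation"`, `"t1"`, `"t2"`,
#'   `"division"`
#' @param m,n tissue dimensions (ignored for `"translation"`, which uses
#'   15 x 8 per its definition)
#' @param g,nLloyd generator parameters, see [generateTissue()]
#' @param seed integer seed; one RNG stream drives the whole test case
#' @return list with components `mesh1`, `mesh2`, `truth`
#' @export
makeTestCase <- function(type = c("permutation", "translation", "t1", "t2",
                                  "division"),
                         m = 9, n = 9, g = 8, nLloyd = 4, seed = NULL) {
    type <- match.arg(type)
    .withSeed(seed, {
        if (type == "translation") {
            tp <- translationPair(g = g, nLloyd = nLloyd)
            pm <- permuteIds(tp$mesh2)
            tm <- truthMap(pm$truth)
            newTo <- tm$to[match(truthMap(tp$truth)$to, tm$from)]
            return(list(mesh1 = tp$mesh1, mesh2 = pm$mesh,
                        truth = groundTruth(truthMap(tp$truth)$from, newTo)))
        }
        mesh1 <- generateTissue(m, n, g = g, nLloyd = nLloyd)
        centre <- c(m / 2, n / 2)
        if (type == "permutation") {
            pm <- permuteIds(mesh1)
            return(list(mesh1 = mesh1, mesh2 = pm$mesh, truth = pm$truth))
        }
        if (type == "t1") {
            ie <- innerEdges(mesh1)
            if (!nrow(ie)) stop("no applicable inner edge")
            v <- mesh1@vertices
            mids <- cbind(
                (v[as.character(ie$va), 1] + v[as.character(ie$vb), 1]) / 2,
                (v[as.character(ie$va), 2] + v[as.character(ie$vb), 2]) / 2)
            d2c <- (mids[, 1] - centre[1])^2 + (mids[, 2] - centre[2])^2
            e <- ie[which.min(d2c), ]
            mesh2 <- applyT1(mesh1, c(e$va, e$vb))
            pm <- permuteIds(mesh2)
            return(list(mesh1 = mesh1, mesh2 = pm$mesh, truth = pm$truth))
        }
        ## central interior cell for t2 / division
        ce <- cellCentroids(mesh1)
        interior <- setdiff(cellIds(mesh1), boundaryCells(mesh1))
        ci <- match(interior, cellIds(mesh1))
        victim <- interior[which.min((ce[ci, 1] - centre[1])^2 +
                                     (ce[ci, 2] - centre[2])^2)]
        if (type == "t2") {
            mesh2 <- applyT2(mesh1, victim)
            pm <- permuteIds(mesh2)
            return(list(mesh1 = mesh1, mesh2 = pm$mesh,
                        truth = groundTruth(
                            truthMap(pm$truth)$from, truthMap(pm$truth)$to,
                            removed = victim)))
        }
        ## division (retry a degenerate random orientation)
        dv <- NULL
        for (attempt in 1:20) {
            dv <- tryCatch(applyDivision(mesh1, victim),
                           notApplicableError = function(e) NULL)
            if (!is.null(dv)) break
        }
        if (is.null(dv)) stop("could not divide the central cell")
        pm <- permuteIds(dv$mesh)
        tm <- truthMap(pm$truth)
        relab <- function(id) tm$to[match(id, tm$from)]
        rec <- dv$record
        dd <- sort(c(relab(rec$daughter1), relab(rec$daughter2)))
        list(mesh1 = mesh1, mesh2 = pm$mesh,
             truth = groundTruth(
                 tm$from[tm$from != rec$mother &
                         !tm$from %in% c(rec$daughter1, rec$daughter2)],
                 tm$to[tm$from != rec$mother &
                       !tm$from %in% c(rec$daughter1, rec$daughter2)],
                 divisions = data.frame(mother = rec$mother,
                                        daughter1 = dd[1L],
                                        daughter2 = dd[2L])))
    })
}
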