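#' @include tissue-mesh.R
NULL

## ---------------------------------------------------------------------------
## internal per-frame data
##
## The tracker works on a compact indexed representation of each frame:
## cells sorted by id, adjacency lists of integer indices, centroids,
## degrees, boundary flags and precomputed second-order neighbourhoods with
## a cheap structural signature used to prefilter isomorphism candidates.
## ---------------------------------------------------------------------------

.frameData <- function(mesh) {
    ids <- sort(as.integer(names(mesh@cells)))
    n <- length(ids)
    se <- .sharedEdges(mesh)
    se <- se[!is.na(se$cell2), , drop = FALSE]
    i1 <- match(se$cell1, ids)
    i2 <- match(se$cell2, ids)
    adj <- vector("list", n)
    for (k in seq_len(n)) adj[[k]] <- integer()
    if (nrow(se)) {
        key <- paste(pmin(i1, i2), pmax(i1, i2))
        keep <- !duplicated(key)
        a <- pmin(i1, i2)[keep]
        b <- pmax(i1, i2)[keep]
        adj <- split(c(b, a), c(a, b))
        full <- vector("list", n)
        for (k in seq_len(n)) full[[k]] <- integer()
        full[as.integer(names(adj))] <- lapply(adj, function(x)
            sort(unique(x)))
        adj <- full
    }
    deg <- lengths(adj)
    bnd <- rep(FALSE, n)
    bnd[match(boundaryCells(mesh), ids)] <- TRUE
    ord <- match(as.character(ids), names(mesh@cells))
    v <- mesh@vertices
    cent <- t(vapply(mesh@cells[ord], function(vs)
        .polygonCentroid(v[as.character(vs), , drop = FALSE]), numeric(2)))
    nbhd2 <- lapply(seq_len(n), function(i)
        sort(unique(c(i, adj[[i]], unlist(adj[adj[[i]]])))))
    ## structural signature of the order-2 neighbourhood: degrees induced
    ## within the neighbourhood itself (full-mesh degrees would differ
    ## between two frames that truncate the tissue differently)
    sig2 <- vapply(seq_len(n), function(i) {
        nb <- nbhd2[[i]]
        indDeg <- vapply(nb, function(m)
            sum(adj[[m]] %in% nb), integer(1))
        paste(sum(adj[[i]] %in% nb),
              paste(sort(indDeg), collapse = ","), sep = "|")
    }, character(1))
    sig1 <- vapply(seq_len(n), function(i)
        paste(deg[i], paste(sort(deg[adj[[i]]]), collapse = ","),
              sep = "|"), character(1))
    ## order-1 signature with degrees induced within the neighbourhood,
    ## invariant to how a window truncates the cells around the ring
    sig1i <- vapply(seq_len(n), function(i) {
        nb <- c(i, adj[[i]])
        indDeg <- vapply(nb, function(m)
            sum(adj[[m]] %in% nb), integer(1))
        paste(deg[i], paste(sort(indDeg), collapse = ","), sep = "|")
    }, character(1))
    nbhd1bnd <- vapply(seq_len(n), function(i)
        any(bnd[c(i, adj[[i]])]), logical(1))
    nbhd2bnd <- vapply(seq_len(n), function(i)
        any(bnd[nbhd2[[i]]]), logical(1))
    ## neighbours in counter-clockwise order around each cell; the planar
    ## embedding's orientation is preserved between frames and is used to
    ## reject mirror-image matches
    nbOrder <- lapply(seq_len(n), function(i) {
        nb <- adj[[i]]
        ang <- atan2(cent[nb, 2] - cent[i, 2], cent[nb, 1] - cent[i, 1])
        nb[order(ang)]
    })
    ## precomputed local (per-neighbourhood) adjacency lists and CCW
    ## orders, indexed within each neighbourhood's own node set; these are
    ## rebuilt constantly during matching otherwise
    nbhd1 <- lapply(seq_len(n), function(i) sort(c(i, adj[[i]])))
    localise <- function(nodes, lists) {
        lapply(lists[nodes], function(x) {
            y <- match(x, nodes)
            as.integer(y[!is.na(y)])
        })
    }
    lAdj2 <- lapply(nbhd2, localise, adj)
    lOrd2 <- lapply(nbhd2, localise, nbOrder)
    lAdj1 <- lapply(nbhd1, localise, adj)
    lOrd1 <- lapply(nbhd1, localise, nbOrder)
    list(ids = ids, n = n, adj = adj, deg = deg, cent = cent,
         boundary = bnd, nbhd2 = nbhd2, nbhd1 = nbhd1,
         sig2 = sig2, sig1 = sig1, sig1i = sig1i,
         lAdj2 = lAdj2, lOrd2 = lOrd2, lAdj1 = lAdj1, lOrd1 = lOrd1,
         nbhd1TouchesBoundary = nbhd1bnd,
         nbhd2TouchesBoundary = nbhd2bnd,
         nbOrder = nbOrder,
         meanLen = sqrt(mean(cellAreas(mesh))))
}

.distMatrix <- function(f1, f2) {
    dx <- outer(f1$cent[, 1], f2$cent[, 1], "-")
    dy <- outer(f1$cent[, 2], f2$cent[, 2], "-")
    sqrt(dx * dx + dy * dy)
}

## fixed-assignment vectors tying a local neighbourhood search to the
## global mapping: nodes already tracked globally may only appear in the
## local MCS paired with their global partner
.localFixed <- function(nodes1, nodes2, map1, map2) {
    f1 <- integer(length(nodes1))
    tr <- !is.na(map1[nodes1])
    if (any(tr)) {
        pos <- match(map1[nodes1[tr]], nodes2)
        f1[tr] <- ifelse(is.na(pos), -1L, pos)
    }
    f2 <- integer(length(nodes2))
    tr2 <- !is.na(map2[nodes2])
    if (any(tr2)) {
        pos <- match(map2[nodes2[tr2]], nodes1)
        f2[tr2] <- ifelse(is.na(pos), -1L, pos)
    }
    list(f1 = f1, f2 = f2)
}

.localAdj <- function(f, nodes) {
    lapply(nodes, function(u) {
        x <- match(f$adj[[u]], nodes)
        as.integer(x[!is.na(x)])
    })
}

## per-node CCW neighbour order restricted to the local node set
.localOrd <- function(f, nodes) {
    lapply(nodes, function(u) {
        x <- match(f$nbOrder[[u]], nodes)
        as.integer(x[!is.na(x)])
    })
}

## anchored local MCS between the order-2 neighbourhoods of v1 (frame 1)
## and c2 (frame 2), consistent with the global mapping; returns the
## mapping size and whether all first-order neighbours of v1 are covered
.scoreLocal <- function(f1, f2, v1, c2, map1, map2, dmat, dmaxAbs,
                        requireFull = FALSE, order1 = FALSE) {
    if (order1) {
        nodes1 <- f1$nbhd1[[v1]]
        nodes2 <- f2$nbhd1[[c2]]
        la1 <- f1$lAdj1[[v1]]; lo1 <- f1$lOrd1[[v1]]
        la2 <- f2$lAdj1[[c2]]; lo2 <- f2$lOrd1[[c2]]
    } else {
        nodes1 <- f1$nbhd2[[v1]]
        nodes2 <- f2$nbhd2[[c2]]
        la1 <- f1$lAdj2[[v1]]; lo1 <- f1$lOrd2[[v1]]
        la2 <- f2$lAdj2[[c2]]; lo2 <- f2$lOrd2[[c2]]
    }
    fx <- .localFixed(nodes1, nodes2, map1, map2)
    lm <- .localMCSCpp(la1, la2,
                       match(v1, nodes1), match(c2, nodes2),
                       fx$f1, fx$f2,
                       dmat[nodes1, nodes2, drop = FALSE], dmaxAbs,
                       lo1, lo2,
                       requireFull,
                       nodeBudget = if (requireFull) 5e3 else 3e3)
    size <- sum(lm > 0L)
    nMissing <- sum(lm[match(f1$adj[[v1]], nodes1)] == 0L)
    list(size = size, covered = nMissing == 0L, nMissing = nMissing,
         full = size == length(nodes1) && size == length(nodes2),
         nodes1 = nodes1, nodes2 = nodes2, map = lm)
}

## ---------------------------------------------------------------------------
## seed finding
## ---------------------------------------------------------------------------

.findSeedIdx <- function(f1, f2, dmat, dmaxAbs, map1, map2,
                         allowed1 = NULL, allowed2 = NULL,
                         excludePairs = character(), isoCache = NULL) {
    cand1 <- if (is.null(allowed1)) seq_len(f1$n) else sort(allowed1)
    avail2 <- if (is.null(allowed2)) seq_len(f2$n) else sort(allowed2)
    ## isomorphism outcomes with an empty mapping are reusable across
    ## repeated seeding attempts. A cached FALSE stays valid even once the
    ## mapping constrains the search (constraints only remove solutions),
    ## so constrained calls may read FALSE results but write nothing.
    unconstrained <- !any(!is.na(map1))
    isoTest <- function(v1, c2, order1) {
        if (is.null(isoCache))
            return(.scoreLocal(f1, f2, v1, c2, map1, map2, dmat, dmaxAbs,
                               requireFull = TRUE, order1 = order1)$full)
        key <- paste(v1, c2, order1)
        hitVal <- isoCache[[key]]
        if (!is.null(hitVal) && (!hitVal || unconstrained))
            return(hitVal)
        val <- .scoreLocal(f1, f2, v1, c2, map1, map2, dmat, dmaxAbs,
                           requireFull = TRUE, order1 = order1)$full
        if (unconstrained) isoCache[[key]] <- val
        val
    }
    ## cells whose second-order neighbourhood stays clear of the tissue
    ## boundary make the strongest seeds (small boundary neighbourhoods
    ## match each other too easily), so scan those first
    int1 <- !f1$nbhd2TouchesBoundary[cand1]
    cand1 <- c(cand1[int1], cand1[!int1])
    ## structure-compatible base pools (signature + degree + distance) do
    ## not depend on the mapping, so they are shared across calls through
    ## the cache environment
    basePools <- function(slot, compute) {
        if (is.null(isoCache)) return(compute())
        bp <- isoCache[[slot]]
        if (is.null(bp)) {
            bp <- compute()
            isoCache[[slot]] <- bp
        }
        bp
    }
    base2 <- basePools(".base2", function() {
        groups <- split(seq_len(f2$n), f2$sig2)
        lapply(seq_len(f1$n), function(v1) {
            g <- groups[[f1$sig2[v1]]]
            if (is.null(g)) return(integer())
            g[f2$deg[g] == f1$deg[v1] & dmat[v1, g] <= dmaxAbs]
        })
    })
    avail2Mask <- logical(f2$n)
    avail2Mask[avail2] <- TRUE
    ## pass 1: identical second-order neighbourhood structure. Cells are
    ## scanned by increasing number of structure-compatible candidates:
    ## a rare neighbourhood signature is far more specific than a common
    ## (near-hexagonal) one, and cells with a unique isomorphic partner
    ## are preferred over ambiguous ones
    pools <- lapply(base2[cand1], function(g) g[avail2Mask[g]])
    nzero <- lengths(pools) > 0L
    o <- order(lengths(pools)[nzero])
    cand1p <- cand1[nzero][o]
    pools <- pools[nzero][o]
    ## a unique isomorphic partner can still be wrong when the cell's own
    ## neighbourhood changed (near a removal or division site); a seed is
    ## therefore corroborated by consensus among several unique matches:
    ## the one whose displacement agrees with the most others wins. Only
    ## the unconstrained initial seeding needs this (and can afford it).
    uniques <- NULL
    ambiguous <- NULL
    for (k in seq_along(cand1p)) {
        v1 <- cand1p[k]
        pool <- pools[[k]]
        hit <- integer()
        for (c2 in pool) {
            if (paste(v1, c2) %in% excludePairs) next
            if (isoTest(v1, c2, order1 = FALSE)) {
                hit <- c(hit, c2)
                ## for the first ambiguous cell, scan its candidates
                ## completely so the closest one can be preferred
                if (length(hit) > 1L && !is.null(ambiguous)) break
            }
        }
        if (length(hit) == 1L) {
            if (!unconstrained) return(c(v1, hit))
            uniques <- rbind(uniques, c(v1, hit))
            if (nrow(uniques) >= 6L) break
        }
        if (length(hit) > 1L && is.null(ambiguous))
            ambiguous <- c(v1, hit[which.min(dmat[v1, hit])])
    }
    if (!is.null(uniques)) {
        if (nrow(uniques) == 1L) return(uniques[1L, ])
        dx <- f2$cent[uniques[, 2L], 1L] - f1$cent[uniques[, 1L], 1L]
        dy <- f2$cent[uniques[, 2L], 2L] - f1$cent[uniques[, 1L], 2L]
        support <- vapply(seq_len(nrow(uniques)), function(i)
            sum(abs(dx - dx[i]) < 0.5 * f1$meanLen &
                abs(dy - dy[i]) < 0.5 * f1$meanLen), integer(1))
        return(uniques[which.max(support), ])
    }
    ## an ambiguous match (several isomorphic partners) is only worth
    ## gambling on for the initial seed, where the caller validates the
    ## whole attempt; amid an ongoing extension a coin-flip island would
    ## go unchecked, so only unique matches are accepted there. Among the
    ## ambiguous candidates the closest centroid is tried first (the next
    ## ones follow through the retry mechanism).
    if (!is.null(ambiguous) && unconstrained) return(ambiguous)
    ## pass 2: first-order neighbourhood only, away from the tissue
    ## boundary, again scanning rare neighbourhood signatures first
    cand1b <- cand1[!f1$nbhd1TouchesBoundary[cand1]]
    base1 <- basePools(".base1", function() {
        groups <- split(seq_len(f2$n), f2$sig1)
        lapply(seq_len(f1$n), function(v1) {
            g <- groups[[f1$sig1[v1]]]
            if (is.null(g)) return(integer())
            g[!f2$nbhd1TouchesBoundary[g] & dmat[v1, g] <= dmaxAbs]
        })
    })
    pools <- lapply(base1[cand1b], function(g) g[avail2Mask[g]])
    nzero <- lengths(pools) > 0L
    o <- order(lengths(pools)[nzero])
    cand1b <- cand1b[nzero][o]
    pools <- pools[nzero][o]
    ambiguous <- NULL
    for (k in seq_along(cand1b)) {
        v1 <- cand1b[k]
        hit <- integer()
        for (c2 in pools[[k]]) {
            if (paste(v1, c2) %in% excludePairs) next
            if (isoTest(v1, c2, order1 = TRUE)) {
                hit <- c(hit, c2)
                if (length(hit) > 1L && !is.null(ambiguous)) break
            }
        }
        if (length(hit) == 1L) return(c(v1, hit))
        if (length(hit) > 1L && is.null(ambiguous))
            ambiguous <- c(v1, hit[which.min(dmat[v1, hit])])
    }
    if (!is.null(ambiguous) && unconstrained) return(ambiguous)
    if (!unconstrained) return(NULL)
    ## pass 3: order-1 isomorphism anywhere in the tissue. When the two
    ## frames are differently truncated windows no cell may survive the
    ## stricter passes; boundary-adjacent seeds are weak individually, so
    ## all order-1-isomorphic pairs are ranked once by the size of their
    ## *partial* second-order MCS (a true correspondence retains most of
    ## its wider neighbourhood, a coincidental one does not), and the
    ## caller validates each attempt through extension, cleaning and
    ## displacement coherence.
    rank3 <- basePools(".pass3rank", function() {
        groups <- split(seq_len(f2$n), f2$sig1i)
        out <- NULL
        tested <- 0L
        for (v1 in seq_len(f1$n)) {
            g <- groups[[f1$sig1i[v1]]]
            if (is.null(g)) next
            g <- g[dmat[v1, g] <= dmaxAbs]
            for (c2 in g) {
                if (tested >= 3000L) break
                tested <- tested + 1L
                sc <- .scoreLocal(f1, f2, v1, c2, map1, map2, dmat,
                                  dmaxAbs, requireFull = TRUE,
                                  order1 = TRUE)
                if (!sc$full) next
                s2 <- .scoreLocal(f1, f2, v1, c2, map1, map2, dmat,
                                  dmaxAbs)
                out <- rbind(out, c(v1, c2, s2$size))
            }
        }
        if (is.null(out)) return(matrix(integer(), 0, 3))
        ## displacement-consensus voting: pairs belonging to the true
        ## correspondence share a common displacement vector (the tissue
        ## moves as a deforming whole), while coincidental matches
        ## scatter; rank by support first, neighbourhood score second
        dx <- f2$cent[out[, 2L], 1L] - f1$cent[out[, 1L], 1L]
        dy <- f2$cent[out[, 2L], 2L] - f1$cent[out[, 1L], 2L]
        support <- vapply(seq_len(nrow(out)), function(i)
            sum(abs(dx - dx[i]) < 1 & abs(dy - dy[i]) < 1), integer(1))
        out[order(-support, -out[, 3L], out[, 1L], out[, 2L]), ,
            drop = FALSE]
    })
    if (nrow(rank3)) {
        cand1Mask <- logical(f1$n)
        cand1Mask[cand1] <- TRUE
        for (k in seq_len(nrow(rank3))) {
            v1 <- rank3[k, 1L]
            c2 <- rank3[k, 2L]
            if (!cand1Mask[v1] || !avail2Mask[c2]) next
            if (paste(v1, c2) %in% excludePairs) next
            ## the ranking was computed against an empty mapping; under a
            ## partial mapping, re-verify consistency before committing
            if (!unconstrained &&
                !.scoreLocal(f1, f2, v1, c2, map1, map2, dmat, dmaxAbs,
                             requireFull = TRUE, order1 = TRUE)$full) next
            return(c(v1, c2))
        }
    }
    NULL
}

## Is the displacement field of a tracked state locally smooth? Tissues
## deform smoothly between frames, so the displacement of a cell should
## resemble that of at least one tracked neighbour; a spurious alignment
## (for example a patch mapped onto a structurally similar patch elsewhere,
## or a point-reflected match in near-homogeneous tissue) produces
## displacements that jump by more than a cell length between neighbours.
.displacementCoherent <- function(map1, f1, f2, tol, maxBadFrac = 0.2) {
    i <- which(!is.na(map1))
    if (length(i) < 2L) return(TRUE)
    disp <- f2$cent[map1[i], , drop = FALSE] - f1$cent[i, , drop = FALSE]
    pos <- integer(f1$n)
    pos[i] <- seq_along(i)
    dev <- vapply(seq_along(i), function(k) {
        nb <- f1$adj[[i[k]]]
        nb <- pos[nb[!is.na(map1[nb])]]
        if (!length(nb)) return(0)
        min(sqrt((disp[nb, 1] - disp[k, 1])^2 +
                 (disp[nb, 2] - disp[k, 2])^2))
    }, numeric(1))
    mean(dev > tol) <= maxBadFrac
}

## ---------------------------------------------------------------------------
## iterative extension
## ---------------------------------------------------------------------------

## candidate partners for frontier cell v1: untracked frame-2 cells with
## the same neighbour count, within the displacement cutoff, adjacent to
## the image of every tracked neighbour of v1
.candidatesFor <- function(v1, f1, f2, map1, map2, dmat, dmaxAbs) {
    tn <- f1$adj[[v1]][!is.na(map1[f1$adj[[v1]]])]
    if (!length(tn)) return(integer())
    cand <- f2$adj[[map1[tn[1L]]]]
    for (t in tn[-1L]) {
        cand <- cand[cand %in% f2$adj[[map1[t]]]]
        if (!length(cand)) return(integer())
    }
    cand <- cand[is.na(map2[cand]) & f2$deg[cand] == f1$deg[v1] &
                 dmat[v1, cand] <= dmaxAbs]
    cand
}

.extendEngine <- function(f1, f2, dmat, dmaxAbs, seedIdx,
                          isoCache = NULL) {
    map1 <- rep(NA_integer_, f1$n)
    map2 <- rep(NA_integer_, f2$n)
    prov <- rep(NA_character_, f1$n)
    ## cached candidate sets per frontier cell; a cell's set is recomputed
    ## when one of its neighbours becomes tracked (tighter connection
    ## constraints), and taken candidates are filtered out lazily
    candCache <- vector("list", f1$n)
    addPair <- function(v1, c2, p) {
        map1[v1] <<- c2
        map2[c2] <<- v1
        prov[v1] <<- p
        frontier[v1] <<- FALSE
        nb <- f1$adj[[v1]]
        un <- nb[is.na(map1[nb])]
        frontier[un] <<- TRUE
        candCache[un] <<- list(NULL)
    }
    frontier <- rep(FALSE, f1$n)
    addPair(seedIdx[1L], seedIdx[2L], "seed")
    repeat {
        fr <- which(frontier)
        if (!length(fr)) {
            ## no adjacent extension possible: search among untracked,
            ## non-adjacent cells by re-running the seeding procedure
            open1 <- which(is.na(map1) & !frontier)
            open2 <- which(is.na(map2))
            if (!length(open1) || !length(open2)) break
            s <- .findSeedIdx(f1, f2, dmat, dmaxAbs, map1, map2,
                              allowed1 = open1, allowed2 = open2,
                              isoCache = isoCache)
            if (is.null(s)) break
            addPair(s[1L], s[2L], "mcs")
            next
        }
        cand <- lapply(fr, function(v1) {
            cc <- candCache[[v1]]
            if (is.null(cc)) {
                cc <- .candidatesFor(v1, f1, f2, map1, map2, dmat, dmaxAbs)
                candCache[[v1]] <<- cc
            }
            cc[is.na(map2[cc])]
        })
        nc <- lengths(cand)
        empty <- nc == 0L
        if (any(empty)) {
            frontier[fr[empty]] <- FALSE
            if (all(empty)) next
        }
        k <- which(!empty)[which.min(nc[!empty])]
        v1 <- fr[k]
        cs <- cand[[k]]
        bestScore <- -1L
        bestDist <- Inf
        best <- NA_integer_
        bestMissing <- Inf
        for (c2 in cs) {
            sc <- .scoreLocal(f1, f2, v1, c2, map1, map2, dmat, dmaxAbs)
            d <- dmat[v1, c2]
            if (sc$size > bestScore ||
                (sc$size == bestScore && d < bestDist)) {
                bestScore <- sc$size
                bestDist <- d
                best <- c2
                bestMissing <- sc$nMissing
            }
        }
        ## the winning pairing must account for the cell's complete
        ## first-order neighbourhood; cells around rearrangement sites
        ## fail this and are deliberately left to post-processing
        if (bestMissing == 0) {
            addPair(v1, best, "mcs")
        } else {
            ## excluding the cell keeps more of its neighbourhood in the
            ## local MCS than any candidate pairing: skip it (it may be
            ## revisited when further neighbours become tracked)
            frontier[v1] <- FALSE
        }
    }
    list(map1 = map1, map2 = map2, prov = prov)
}

## preserved tracked-neighbour connections of every mapped cell: the number
## of neighbours in frame 1 that are themselves tracked and whose images
## are adjacent to the cell's image in frame 2
.preservedCounts <- function(f1, f2, map1) {
    vapply(seq_len(f1$n), function(i) {
        if (is.na(map1[i])) return(NA_integer_)
        nb <- f1$adj[[i]]
        tn <- nb[!is.na(map1[nb])]
        if (!length(tn)) return(0L)
        sum(map1[tn] %in% f2$adj[[map1[i]]])
    }, integer(1))
}

.cleanEngine <- function(state, f1, f2, cfg) {
    map1 <- state$map1
    pc <- .preservedCounts(f1, f2, map1)
    weak <- which(!is.na(map1) & pc < cfg@minConnections)
    map1[weak] <- NA_integer_
    ## remove small isolated clusters of the preserved-adjacency subgraph
    tracked <- which(!is.na(map1))
    if (length(tracked)) {
        ep <- do.call(rbind, lapply(tracked, function(i) {
            nb <- f1$adj[[i]]
            nb <- nb[nb > i & !is.na(map1[nb])]
            nb <- nb[map1[nb] %in% f2$adj[[map1[i]]]]
            if (length(nb)) cbind(i, nb) else NULL
        }))
        g <- igraph::make_empty_graph(length(tracked), directed = FALSE)
        if (!is.null(ep))
            g <- igraph::add_edges(g, rbind(match(ep[, 1], tracked),
                                            match(ep[, 2], tracked)))
        comp <- igraph::components(g)
        small <- which(comp$csize[comp$membership] < cfg@minClusterSize)
        map1[tracked[small]] <- NA_integer_
    }
    map2 <- rep(NA_integer_, f2$n)
    map2[map1[!is.na(map1)]] <- which(!is.na(map1))
    prov <- state$prov
    prov[is.na(map1)] <- NA_character_
    list(map1 = map1, map2 = map2, prov = prov)
}

## ---------------------------------------------------------------------------
## exported operations
## ---------------------------------------------------------------------------

#' Find an initial match (seed) between two frames
#'
#' Scans the first frame's cells in id order for a cell whose second-order
#' neighbourhood network is isomorphic (with the centre cells anchored and
#' compatible neighbour counts) to that of a cell in the second frame
#' within the displacement cutoff. If no such pair exists, falls back to
#' first-order neighbourhood isomorphism restricted to cells whose
#' neighbourhood does not touch the tissue boundary. Returns `NULL` when
#' both passes fail, which callers should report as a tracking failure.
#'
#' @param mesh1,mesh2 [CellMesh-class] objects for the two frames
#' @param config a [TrackerConfig-class]
#' @return integer vector `c(from, to)` of cell ids, or `NULL`
#' @export
findSeed <- function(mesh1, mesh2, config = trackerConfig()) {
    f1 <- .frameData(mesh1)
    f2 <- .frameData(mesh2)
    dmat <- .distMatrix(f1, f2)
    s <- .findSeedIdx(f1, f2, dmat, config@dMax * f1$meanLen,
                      rep(NA_integer_, f1$n), rep(NA_integer_, f2$n))
    if (is.null(s)) NULL else c(f1$ids[s[1L]], f2$ids[s[2L]])
}

#' Exact local maximum common subgraph between two neighbourhood graphs
#'
#' Computes the largest common connected induced subgraph between two small
#' neighbourhood graphs (as returned by [neighbourhoodGraph()]), anchored
#' at their centre cells, by exact branch and bound. The size of this local
#' MCS is the score used to rank candidate matches during tracking; working
#' on neighbourhood graphs of at most a few dozen cells is what makes the
#' otherwise NP-hard MCS computation tractable.
#'
#' @param nbhd1,nbhd2 igraph graphs with a logical vertex attribute
#'   `centre` marking exactly one vertex each
#' @return a [CellMapping-class] pairing cell ids of `nbhd1` with cell ids
#'   of `nbhd2`
#' @export
localMCS <- function(nbhd1, nbhd2) {
    a1 <- which(igraph::V(nbhd1)$centre)
    a2 <- which(igraph::V(nbhd2)$centre)
    if (length(a1) != 1L || length(a2) != 1L)
        stop("each neighbourhood graph needs exactly one centre vertex")
    adj1 <- lapply(seq_len(igraph::vcount(nbhd1)), function(i)
        as.integer(igraph::neighbors(nbhd1, i)))
    adj2 <- lapply(seq_len(igraph::vcount(nbhd2)), function(i)
        as.integer(igraph::neighbors(nbhd2, i)))
    ## no geometry available for plain graphs: no orientation constraint
    noOrd1 <- rep(list(integer()), length(adj1))
    noOrd2 <- rep(list(integer()), length(adj2))
    lm <- .localMCSCpp(adj1, adj2, a1, a2,
                       integer(length(adj1)), integer(length(adj2)),
                       matrix(0, 0, 0), Inf,
                       noOrd1, noOrd2, FALSE)
    hit <- which(lm > 0L)
    cellMapping(as.integer(igraph::V(nbhd1)$name[hit]),
                as.integer(igraph::V(nbhd2)$name[lm[hit]]),
                "mcs")
}

#' Iteratively extend a seed match to a maximum common subgraph
#'
#' Starting from the seed pair, repeatedly selects the untracked frame-1
#' cell adjacent to the current common subgraph with the fewest potential
#' matches; candidates are frame-2 cells with the same neighbour count that
#' preserve the connections to already tracked cells and lie within the
#' displacement cutoff. The candidate whose second-order neighbourhood
#' yields the largest anchored local MCS wins (ties resolved by centroid
#' distance); a cell whose best pairing fails to account for its complete
#' first-order neighbourhood is excluded for now and may be revisited as
#' the subgraph grows. When no adjacent cell can be added, the seeding
#' procedure is re-run among untracked cells before giving up.
#'
#' @param seed integer vector `c(from, to)` as returned by [findSeed()]
#' @param mesh1,mesh2 the two frames
#' @param config a [TrackerConfig-class]
#' @return a [CellMapping-class] with provenance `"seed"`/`"mcs"`
#' @export
extendMCS <- function(seed, mesh1, mesh2, config = trackerConfig()) {
    f1 <- .frameData(mesh1)
    f2 <- .frameData(mesh2)
    dmat <- .distMatrix(f1, f2)
    st <- .extendEngine(f1, f2, dmat, config@dMax * f1$meanLen,
                        c(match(seed[1L], f1$ids), match(seed[2L], f2$ids)))
    .stateToMapping(st, f1, f2)
}

#' Clean a raw maximum common subgraph mapping
#'
#' Removes pairs with fewer than `minConnections` tracked neighbours whose
#' adjacency is preserved in both frames, then discards connected
#' components of the preserved-adjacency subgraph smaller than
#' `minClusterSize` cells. Both steps remove the weakly supported matches
#' for which connectivity carries too little information, which is where
#' MCS tracking errors concentrate.
#'
#' @param mapping a [CellMapping-class] from [extendMCS()]
#' @param mesh1,mesh2 the two frames
#' @param config a [TrackerConfig-class]
#' @return the cleaned [CellMapping-class] (possibly empty)
#' @export
cleanMCS <- function(mapping, mesh1, mesh2, config = trackerConfig()) {
    f1 <- .frameData(mesh1)
    f2 <- .frameData(mesh2)
    st <- .mappingToState(mapping, f1, f2)
    .stateToMapping(.cleanEngine(st, f1, f2, config), f1, f2)
}

.stateToMapping <- function(state, f1, f2) {
    i <- which(!is.na(state$map1))
    cellMapping(f1$ids[i], f2$ids[state$map1[i]], state$prov[i])
}

.mappingToState <- function(mapping, f1, f2) {
    p <- mapping@pairs
    map1 <- rep(NA_integer_, f1$n)
    map2 <- rep(NA_integer_, f2$n)
    prov <- rep(NA_character_, f1$n)
    i <- match(p$from, f1$ids)
    j <- match(p$to, f2$ids)
    if (anyNA(i) || anyNA(j))
        stop("mapping refers to cells absent from the meshes")
    map1[i] <- j
    map2[j] <- i
    prov[i] <- p$provenance
    list(map1 = map1, map2 = map2, prov = prov)
}
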