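#' @include mcs-core.R
NULL

## ---------------------------------------------------------------------------
## post-processing engine
## ---------------------------------------------------------------------------

## number of tracked neighbours of u1 whose images are adjacent to u2
.preservedFor <- function(u1, u2, f1, f2, map1) {
    nb <- f1$adj[[u1]]
    tn <- nb[!is.na(map1[nb])]
    if (!length(tn)) return(0L)
    sum(map1[tn] %in% f2$adj[[u2]])
}

## tracked neighbours u2 gains: tracked cells adjacent to u2 in frame 2
## whose preimages were not adjacent to u1 in frame 1
.gainedFor <- function(u1, u2, f1, f2, map2) {
    nb2 <- f2$adj[[u2]]
    tn2 <- nb2[!is.na(map2[nb2])]
    if (!length(tn2)) return(0L)
    sum(!(map2[tn2] %in% f1$adj[[u1]]))
}

## cyclic orientation of the preserved neighbours around u1 must match the
## orientation of their images around u2 (planar tissues do not mirror)
.orientationOK <- function(u1, u2, f1, f2, map1) {
    o1 <- f1$nbOrder[[u1]]
    imgs <- map1[o1]
    keep <- !is.na(imgs) & imgs %in% f2$adj[[u2]]
    if (sum(keep) < 3L) return(TRUE)
    s <- match(imgs[keep], f2$nbOrder[[u2]])
    descents <- sum(diff(c(s, s[1L])) < 0)
    descents <= 1L
}

.postEngine <- function(state, f1, f2, dmat, dmaxAbs, cfg) {
    map1 <- state$map1
    map2 <- state$map2
    prov <- state$prov
    ## per-cell best candidate, recomputed lazily: a cell's evaluation
    ## changes only when one of its neighbours becomes tracked (preserved
    ## counts and candidate pool) or when its cached partner or one of
    ## that partner's neighbours is taken (availability and gained counts)
    bestFor <- function(u1) {
        nb <- f1$adj[[u1]]
        tn <- nb[!is.na(map1[nb])]
        if (length(tn) < cfg@postMinNeighbours) return(NULL)
        cand <- unique(unlist(f2$adj[map1[tn]]))
        ## events change a cell's neighbour count by one or two; a larger
        ## jump marks a structurally different cell (for example a
        ## clipped fragment at the field-of-view edge)
        cand <- cand[is.na(map2[cand]) & dmat[u1, cand] <= dmaxAbs &
                     abs(f2$deg[cand] - f1$deg[u1]) <= 3L]
        bP <- -1L
        bD <- Inf
        bU2 <- NA_integer_
        for (u2 in cand) {
            p <- .preservedFor(u1, u2, f1, f2, map1)
            if (p < cfg@postMinNeighbours || p < bP) next
            if (.gainedFor(u1, u2, f1, f2, map2) > p) next
            if (!.orientationOK(u1, u2, f1, f2, map1)) next
            d <- dmat[u1, u2]
            if (p > bP || d < bD) {
                bP <- p
                bD <- d
                bU2 <- u2
            }
        }
        if (is.na(bU2)) NULL else c(bU2, bP, bD)
    }
    cache <- vector("list", f1$n)
    stale <- rep(TRUE, f1$n)
    repeat {
        u1s <- which(is.na(map1))
        if (!length(u1s)) break
        for (u1 in u1s[stale[u1s]]) {
            cache[u1] <- list(bestFor(u1))
            stale[u1] <- FALSE
        }
        bestPair <- NULL
        bestP <- -1L
        bestD <- Inf
        for (u1 in u1s) {
            cc <- cache[[u1]]
            if (is.null(cc)) next
            if (cc[2L] > bestP || (cc[2L] == bestP && cc[3L] < bestD)) {
                bestP <- cc[2L]
                bestD <- cc[3L]
                bestPair <- c(u1, cc[1L])
            }
        }
        if (is.null(bestPair)) break
        a <- bestPair[1L]
        b <- bestPair[2L]
        map1[a] <- b
        map2[b] <- a
        prov[a] <- "post"
        stale[f1$adj[[a]]] <- TRUE
        nbB <- c(b, f2$adj[[b]])
        for (u1 in u1s) {
            cc <- cache[[u1]]
            if (!is.null(cc) && cc[1L] %in% nbB) stale[u1] <- TRUE
        }
    }
    list(map1 = map1, map2 = map2, prov = prov)
}

## Local refinement: a mapped cell is re-paired when an untracked
## second-frame cell supports strictly more preserved tracked-neighbour
## connections than its current partner. Transient mistakes made early in
## the extension (before the surrounding context was tracked) survive
## cleaning only in locally symmetric tissue; with the full mapping in
## hand they are dominated by the true partner and corrected here. Total
## preserved-connection count strictly increases with every swap, so the
## pass terminates.
.refineEngine <- function(state, f1, f2, dmat, dmaxAbs, cfg) {
    map1 <- state$map1
    map2 <- state$map2
    prov <- state$prov
    repeat {
        changed <- FALSE
        for (u1 in which(!is.na(map1))) {
            p0 <- .preservedFor(u1, map1[u1], f1, f2, map1)
            nb <- f1$adj[[u1]]
            tn <- nb[!is.na(map1[nb])]
            if (!length(tn)) next
            cand <- unique(unlist(f2$adj[map1[tn]]))
            cand <- cand[is.na(map2[cand]) & dmat[u1, cand] <= dmaxAbs &
                         abs(f2$deg[cand] - f1$deg[u1]) <= 3L]
            bestP <- p0
            bestD <- dmat[u1, map1[u1]]
            best <- NA_integer_
            for (u2 in cand) {
                p <- .preservedFor(u1, u2, f1, f2, map1)
                if (p <= bestP) next
                if (.gainedFor(u1, u2, f1, f2, map2) > p) next
                if (!.orientationOK(u1, u2, f1, f2, map1)) next
                bestP <- p
                bestD <- dmat[u1, u2]
                best <- u2
            }
            if (!is.na(best)) {
                map2[map1[u1]] <- NA_integer_
                map1[u1] <- best
                map2[best] <- u1
                prov[u1] <- "post"
                changed <- TRUE
            }
        }
        if (!changed) break
    }
    list(map1 = map1, map2 = map2, prov = prov)
}

## Final smoothness pruning: remove mapped pairs whose displacement
## differs from that of every tracked neighbour by more than tol. A
## correctly tracked cell always has a neighbour moving with it; members
## of a spurious self-consistent patch (for example a point-reflected
## alignment in near-homogeneous tissue) disagree with all neighbours —
## including each other, since a rotation changes relative displacements
## by about twice the neighbour spacing.
.pruneIncoherent <- function(state, f1, f2, tol) {
    map1 <- state$map1
    i <- which(!is.na(map1))
    if (length(i) < 2L) return(state)
    disp <- f2$cent[map1[i], , drop = FALSE] - f1$cent[i, , drop = FALSE]
    pos <- integer(f1$n)
    pos[i] <- seq_along(i)
    bad <- vapply(seq_along(i), function(k) {
        nb <- f1$adj[[i[k]]]
        nb <- pos[nb[!is.na(map1[nb])]]
        if (!length(nb)) return(FALSE)
        min(sqrt((disp[nb, 1] - disp[k, 1])^2 +
                 (disp[nb, 2] - disp[k, 2])^2)) > tol
    }, logical(1))
    if (!any(bad)) return(state)
    drop <- i[bad]
    state$map2[map1[drop]] <- NA_integer_
    state$map1[drop] <- NA_integer_
    state$prov[drop] <- NA_character_
    state
}

## ---------------------------------------------------------------------------
## division resolution engine
## ---------------------------------------------------------------------------

## Divisions leave one more cell in frame 2 than the mapping can absorb, so
## every division produces a cluster of untracked frame-2 cells (possibly a
## single cell, when the mother has been paired with one of its daughters).
## The cells adjacent to a division that gain an edge pin down the mother
## and daughters as their shared neighbours; when network evidence is
## ambiguous (a three- or four-sided daughter) the geometrically closest
## mother/daughter combination wins.
.divisionEngine <- function(state, f1, f2, dmat) {
    map1 <- state$map1
    map2 <- state$map2
    prov <- state$prov
    notes <- character()
    div <- NULL
    un2 <- which(is.na(map2))
    if (!length(un2))
        return(list(map1 = map1, map2 = map2, prov = prov,
                    divisions = div, notes = notes))
    ## connected clusters of untracked frame-2 cells
    comp <- local({
        idx <- match(seq_len(f2$n), un2)
        g <- igraph::make_empty_graph(length(un2), directed = FALSE)
        ep <- do.call(rbind, lapply(seq_along(un2), function(k) {
            nb <- f2$adj[[un2[k]]]
            nb <- idx[nb[nb %in% un2 & nb > un2[k]]]
            if (length(nb)) cbind(k, nb) else NULL
        }))
        if (!is.null(ep)) g <- igraph::add_edges(g, t(ep))
        igraph::components(g)$membership
    })
    for (cid in unique(comp)) {
        cl <- un2[comp == cid]
        ## divisions are interior events: a cluster touching the tissue
        ## boundary is made of cells entering the field of view
        if (any(f2$boundary[cl])) next
        nb2 <- setdiff(unique(unlist(f2$adj[cl])), cl)
        tr2 <- nb2[!is.na(map2[nb2])]
        ## cells adjacent to the cluster that gained an edge
        grey <- tr2[f2$deg[tr2] > f1$deg[map2[tr2]]]
        if (length(grey) < 1L) {
            ## no gained-edge evidence: not a division site (for example a
            ## cell that entered the field of view); leave untracked
            next
        }
        addCombos <- function(combos, D, M, cl) {
            for (m in M) {
                for (x in D[D %in% cl]) {
                    for (y in setdiff(D, x)) {
                        ## daughters share the cleavage edge
                        if (!(y %in% f2$adj[[x]])) next
                        ## the second daughter is either untracked too, or
                        ## currently (wrongly) paired with the mother
                        okY <- is.na(map2[y]) || map2[y] == m
                        okM <- is.na(map1[m]) || map1[m] %in% c(x, y)
                        if (!okY || !okM) next
                        s <- dmat[m, x] + dmat[m, y]
                        combos <- rbind(combos, c(m, x, y, s))
                    }
                }
            }
            combos
        }
        combos <- NULL
        if (length(grey) >= 2L) {
            pairs <- utils::combn(sort(grey), 2L)
            for (k in seq_len(ncol(pairs))) {
                ga <- pairs[1L, k]; gb <- pairs[2L, k]
                combos <- addCombos(combos,
                                    intersect(f2$adj[[ga]], f2$adj[[gb]]),
                                    intersect(f1$adj[[map2[ga]]],
                                              f1$adj[[map2[gb]]]), cl)
            }
        }
        if (is.null(combos)) {
            ## a cut landing on an existing junction (three- or four-sided
            ## daughter) leaves only one cell with a gained edge; both
            ## daughters are still neighbours of that cell
            for (ga in sort(grey))
                combos <- addCombos(combos, f2$adj[[ga]],
                                    f1$adj[[map2[ga]]], cl)
        }
        if (is.null(combos)) {
            notes <- c(notes, sprintf(
                "division not resolved near frame-2 cell %d", f2$ids[cl[1L]]))
            next
        }
        best <- combos[order(combos[, 4L], combos[, 1L],
                             pmin(combos[, 2L], combos[, 3L]))[1L], ]
        m <- best[1L]; d1 <- best[2L]; d2 <- best[3L]
        if (!is.na(map1[m])) {
            map2[map1[m]] <- NA_integer_
            map1[m] <- NA_integer_
            prov[m] <- NA_character_
        }
        ## daughters are taken out of the untracked pool by marking them in
        ## map2 with a sentinel handled by the caller
        div <- rbind(div, data.frame(
            mother = f1$ids[m],
            daughter1 = f2$ids[min(d1, d2)],
            daughter2 = f2$ids[max(d1, d2)],
            motherIdx = m, d1Idx = min(d1, d2), d2Idx = max(d1, d2)))
    }
    list(map1 = map1, map2 = map2, prov = prov, divisions = div,
         notes = notes)
}

## ---------------------------------------------------------------------------
## exported operations
## ---------------------------------------------------------------------------

#' Grow a cleaned mapping by adjacency-guided post-processing
#'
#' Iteratively adds the untracked cell pair with the largest number of
#' preserved tracked-neighbour connections, requiring at least
#' `postMinNeighbours` preserved connections and that a cell does not gain
#' more tracked neighbours between the frames than it preserves. Pairs are
#' only added, never removed, so the tracked set grows monotonically from
#' the cleaned MCS until a fixed point is reached.
#'
#' @param mapping a cleaned [CellMapping-class]
#' @param mesh1,mesh2 the two frames
#' @param config a [TrackerConfig-class]
#' @return the extended [CellMapping-class]
#' @export
postProcess <- function(mapping, mesh1, mesh2, config = trackerConfig()) {
    f1 <- .frameData(mesh1)
    f2 <- .frameData(mesh2)
    dmat <- .distMatrix(f1, f2)
    st <- .postEngine(.mappingToState(mapping, f1, f2), f1, f2, dmat,
                      config@dMax * f1$meanLen, config)
    .stateToMapping(st, f1, f2)
}

#' Resolve division events in a post-processed mapping
#'
#' Identifies division sites from clusters of untracked frame-2 cells and
#' the adjacent cells that gained an edge, removes the mother from the
#' mapping if it had been paired with a daughter, and records
#' (mother, daughter1, daughter2) triples. Unresolvable configurations
#' (for example adjacent simultaneous divisions) are left untracked with a
#' warning.
#'
#' @param mapping a [CellMapping-class] after [postProcess()]
#' @param mesh1,mesh2 the two frames
#' @return a [TrackingResult-class] (deaths not yet filled in)
#' @export
resolveDivisions <- function(mapping, mesh1, mesh2) {
    f1 <- .frameData(mesh1)
    f2 <- .frameData(mesh2)
    dmat <- .distMatrix(f1, f2)
    st <- .divisionEngine(.mappingToState(mapping, f1, f2), f1, f2, dmat)
    .assembleResult(st, f1, f2)
}

#' Detect cell deaths
#'
#' Deaths are untracked frame-1 cells lying in the interior of the tracked
#' region: every neighbour is tracked (or is a division mother) and the
#' cell is not on the tissue boundary. Untracked cells at the boundary are
#' left as untracked, since they may simply have left the field of view.
#'
#' @param result a [TrackingResult-class] from [resolveDivisions()]
#' @param mesh1 the first frame
#' @return the updated [TrackingResult-class]
#' @export
detectDeaths <- function(result, mesh1) {
    f1 <- .frameData(mesh1)
    p <- result@mapping@pairs
    trackedLike <- c(p$from, result@divisions$mother)
    candidates <- setdiff(f1$ids,
                          c(trackedLike, result@deaths,
                            f1$ids[f1$boundary]))
    dead <- candidates[vapply(candidates, function(id) {
        nb <- f1$ids[f1$adj[[match(id, f1$ids)]]]
        length(nb) > 0L && all(nb %in% trackedLike)
    }, logical(1))]
    new("TrackingResult", mapping = result@mapping,
        divisions = result@divisions, deaths = sort(as.integer(dead)),
        untracked1 = setdiff(result@untracked1, dead),
        untracked2 = result@untracked2, notes = result@notes)
}

.assembleResult <- function(st, f1, f2) {
    mapping <- .stateToMapping(st, f1, f2)
    div <- st$divisions
    if (is.null(div))
        div <- data.frame(mother = integer(), daughter1 = integer(),
                          daughter2 = integer())
    else div <- div[, c("mother", "daughter1", "daughter2"), drop = FALSE]
    p <- mapping@pairs
    un1 <- setdiff(f1$ids, c(p$from, div$mother))
    un2 <- setdiff(f2$ids, c(p$to, div$daughter1, div$daughter2))
    .trackingResult(mapping, div, integer(), un1, un2,
                    notes = if (is.null(st$notes)) character() else st$notes)
}

#' Track cells between two segmented frames
#'
#' Runs the full pipeline: seed finding, iterative maximum-common-subgraph
#' extension, cleaning, adjacency-guided post-processing, division
#' resolution and death detection. The returned mapping records for every
#' pair which stage produced it.
#'
#' @param mesh1,mesh2 [CellMesh-class] objects for consecutive frames
#' @param config a [TrackerConfig-class]
#' @return a [TrackingResult-class]
#' @examples
#' tc <- makeTestCase("permutation", m = 6, n = 6, seed = 1)
#' res <- track(tc$mesh1, tc$mesh2)
#' res
#' @export
track <- function(mesh1, mesh2, config = trackerConfig()) {
    f1 <- .frameData(mesh1)
    f2 <- .frameData(mesh2)
    if (f1$n == 0L || f2$n == 0L)
        stop("cannot track empty frames")
    dmat <- .distMatrix(f1, f2)
    dmaxAbs <- config@dMax * f1$meanLen
    ## repeated seeding: a seed is accepted only when its pair survives
    ## the cleaning step (a spurious seed's extension finds little
    ## consistent structure around it) and the cleaned mapping has a
    ## locally smooth displacement field; otherwise retry with the next
    ## seed candidate
    tried <- character()
    noMap <- rep(NA_integer_, f1$n)
    noMap2 <- rep(NA_integer_, f2$n)
    emptyState <- list(map1 = noMap, map2 = noMap2,
                       prov = rep(NA_character_, f1$n))
    st <- emptyState
    bestState <- emptyState
    bestSize <- 0L
    isoCache <- new.env(parent = emptyenv())
    repeat {
        seedIdx <- .findSeedIdx(f1, f2, dmat, dmaxAbs, noMap, noMap2,
                                excludePairs = tried, isoCache = isoCache)
        if (is.null(seedIdx)) {
            if (!length(tried))
                stop(.trackingFailure(
                    "no initial match found between the two frames"))
            st <- bestState
            break
        }
        st <- .extendEngine(f1, f2, dmat, dmaxAbs, seedIdx, isoCache)
        st <- .cleanEngine(st, f1, f2, config)
        coherent <- .displacementCoherent(st$map1, f1, f2,
                                          1.5 * f1$meanLen)
        size <- sum(!is.na(st$map1))
        ## frames with clearly different cell counts have had cells enter
        ## or leave the field of view; there a small coherent alignment
        ## may be a shifted match in a homogeneous strip, so only accept
        ## outright an alignment covering at least half the smaller frame
        ## (otherwise the largest coherent attempt wins at the end)
        decisiveNeeded <- abs(f1$n - f2$n) > 1L
        if (coherent &&
            identical(st$map1[seedIdx[1L]], seedIdx[2L]) &&
            (!decisiveNeeded || size >= 0.5 * min(f1$n, f2$n))) break
        if (coherent && size > bestSize) {
            bestSize <- size
            bestState <- st
        }
        tried <- c(tried, paste(seedIdx[1L], seedIdx[2L]))
        ## each retry costs roughly one extension pass, so allow many
        ## retries on small frames and few on large ones
        if (length(tried) >= max(6L, min(60L, 3000L %/% f1$n))) {
            st <- bestState
            break
        }
    }
    if (!any(!is.na(st$map1)))
        warning("cleaning removed the entire maximum common subgraph")
    ## grow and locally improve to a joint fixed point: refinement can
    ## free second-frame cells that enable further additions
    grow <- function(st) {
        repeat {
            before <- st$map1
            st <- .postEngine(st, f1, f2, dmat, dmaxAbs, config)
            st <- .refineEngine(st, f1, f2, dmat, dmaxAbs, config)
            if (identical(st$map1, before)) return(st)
        }
    }
    st <- grow(st)
    ## discard displacement-incoherent pairs and give the freed cells
    ## another chance at a smooth assignment
    for (round in 1:3) {
        pruned <- .pruneIncoherent(st, f1, f2, 1.5 * f1$meanLen)
        if (identical(pruned$map1, st$map1)) break
        st <- grow(pruned)
    }
    st <- .divisionEngine(st, f1, f2, dmat)
    for (w in st$notes) warning(w, call. = FALSE)
    res <- .assembleResult(st, f1, f2)
    detectDeaths(res, mesh1)
}

.trackingFailure <- function(msg) {
    structure(class = c("trackingFailureError", "error", "condition"),
              list(message = msg, call = sys.call(-1)))
}

#' Track a sequence of frames with persistent track ids
#'
#' Applies [track()] to every consecutive frame pair and chains the
#' mappings into persistent track identifiers. Cells appearing for the
#' first time (including division daughters) receive fresh track ids;
#' daughters are linked to their mother's track in the `lineage` table.
#'
#' @param meshes list of [CellMesh-class] objects, in temporal order
#' @param config a [TrackerConfig-class]
#' @return a list with components `results` (per-pair
#'   [TrackingResult-class]), `tracks` (data.frame `frame`, `cell`,
#'   `track`) and `lineage` (data.frame `track`, `parent`)
#' @export
trackSequence <- function(meshes, config = trackerConfig()) {
    if (length(meshes) < 2L)
        stop("need at least two frames")
    results <- vector("list", length(meshes) - 1L)
    ids1 <- sort(cellIds(meshes[[1L]]))
    trackOf <- stats::setNames(seq_along(ids1), ids1)
    nextTrack <- length(ids1) + 1L
    tracks <- data.frame(frame = 1L, cell = ids1,
                         track = as.integer(trackOf))
    lineage <- data.frame(track = integer(), parent = integer())
    for (k in seq_len(length(meshes) - 1L)) {
        res <- tryCatch(track(meshes[[k]], meshes[[k + 1L]], config),
                        trackingFailureError = function(e)
                            stop("tracking failed between frames ", k,
                                 " and ", k + 1L, ": ", conditionMessage(e),
                                 call. = FALSE))
        results[[k]] <- res
        p <- res@mapping@pairs
        newTrackOf <- integer()
        if (nrow(p))
            newTrackOf[as.character(p$to)] <- trackOf[as.character(p$from)]
        d <- res@divisions
        for (j in seq_len(nrow(d))) {
            parent <- trackOf[as.character(d$mother[j])]
            for (dd in c(d$daughter1[j], d$daughter2[j])) {
                newTrackOf[as.character(dd)] <- nextTrack
                lineage <- rbind(lineage, data.frame(
                    track = nextTrack,
                    parent = as.integer(parent)))
                nextTrack <- nextTrack + 1L
            }
        }
        fresh <- setdiff(as.character(sort(cellIds(meshes[[k + 1L]]))),
                         names(newTrackOf))
        for (id in fresh) {
            newTrackOf[id] <- nextTrack
            nextTrack <- nextTrack + 1L
        }
        trackOf <- newTrackOf
        ids <- sort(as.integer(names(trackOf)))
        tracks <- rbind(tracks, data.frame(
            frame = k + 1L, cell = ids,
            track = as.integer(trackOf[as.character(ids)])))
    }
    list(results = results, tracks = tracks, lineage = lineage)
}
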