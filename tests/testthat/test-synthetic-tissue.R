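test_that("generated tissues have the nominal cell count and unit area", {
    counts <- areas <- numeric(5)
    for (s in 1:5) {
        mesh <- generateTissue(9, 9, seed = s)
        counts[s] <- nCells(mesh)
        areas[s] <- mean(cellAreas(mesh))
        ce <- cellCentroids(mesh)
        ## by construction only polygons with centroids in the central
        ## rectangle are kept
        expect_true(all(ce[, 1] >= 0 & ce[, 1] <= 9 &
                        ce[, 2] >= 0 & ce[, 2] <= 9))
    }
    expect_gt(mean(counts), 81 * 0.85)
    expect_lt(mean(counts), 81 * 1.15)
    expect_equal(mean(areas), 1.0, tolerance = 0.1)
})

test_that("generation is bit-reproducible for a fixed seed", {
    m1 <- generateTissue(6, 6, seed = 42)
    m2 <- generateTissue(6, 6, seed = 42)
    expect_identical(vertexCoords(m1), vertexCoords(m2))
    expect_identical(cellPolygons(m1), cellPolygons(m2))
})

test_that("Lloyd relaxation homogenises the side-number distribution", {
    sideVar <- function(nL) {
        v <- numeric(10)
        for (s in 1:10) {
            mesh <- generateTissue(9, 9, nLloyd = nL, seed = 500 + s)
            f <- epimcs:::.frameData(mesh)
            v[s] <- stats::var(f$deg[!f$boundary])
        }
        mean(v)
    }
    v0 <- sideVar(0)
    v4 <- sideVar(4)
    expect_lt(v4, v0)
    ## hexagon fraction rises towards (but below) the regular-lattice value
    hexFrac <- function(nL) {
        h <- numeric(10)
        for (s in 1:10) {
            mesh <- generateTissue(9, 9, nLloyd = nL, seed = 500 + s)
            f <- epimcs:::.frameData(mesh)
            h[s] <- mean(f$deg[!f$boundary] == 6)
        }
        mean(h)
    }
    h0 <- hexFrac(0)
    h4 <- hexFrac(4)
    expect_gt(h4, h0)
    expect_lt(h4, 1)
})

test_that("id permutation preserves geometry and composes algebraically", {
    mesh <- generateTissue(6, 6, seed = 11)
    pm <- permuteIds(mesh, seed = 1)
    tm <- truthMap(pm$truth)
    ## identical geometry under the map
    a1 <- cellAreas(mesh)
    a2 <- cellAreas(pm$mesh)
    expect_equal(unname(a2[as.character(tm$to)]),
                 unname(a1[as.character(tm$from)]))
    ## applying the inverse map recovers the original ids
    inv <- stats::setNames(tm$from, tm$to)
    cells2 <- cellPolygons(pm$mesh)
    names(cells2) <- as.character(inv[names(cells2)])
    expect_equal(cells2[order(as.integer(names(cells2)))],
                 cellPolygons(mesh)[order(as.integer(names(cellPolygons(mesh))))])
    ## composition of two shuffles equals the composed map
    pm2 <- permuteIds(pm$mesh, seed = 2)
    tm2 <- truthMap(pm2$truth)
    composed <- tm2$to[match(tm$to, tm2$from)]
    direct <- cellPolygons(pm2$mesh)
    expect_equal(sort(composed), sort(truthMap(pm2$truth)$to))
    for (k in seq_len(nrow(tm))) {
        expect_equal(direct[[as.character(composed[k])]],
                     cellPolygons(mesh)[[as.character(tm$from[k])]])
    }
})

test_that("translation pairs share the expected window overlap", {
    tp <- translationPair(seed = 3)
    tm <- truthMap(tp$truth)
    ## overlap width 5 of height 8: about 40 shared cells
    expect_gt(nrow(tm), 25)
    expect_lt(nrow(tm), 55)
    expect_false(any(duplicated(tm$from)))
    expect_false(any(duplicated(tm$to)))
    ## both windows re-anchored at x = 0
    expect_equal(min(vertexCoords(tp$mesh1)[, 1]), 0)
    expect_equal(min(vertexCoords(tp$mesh2)[, 1]), 0)
    ## zero offset: the two windows are identical and the ground truth
    ## covers every cell whose centroid lies inside the window (clipped
    ## boundary slivers are part of the meshes but not of the truth)
    tp0 <- translationPair(seed = 3, offset = 0)
    expect_equal(cellPolygons(tp0$mesh1), cellPolygons(tp0$mesh2))
    tm0 <- truthMap(tp0$truth)
    expect_equal(tm0$from, tm0$to)
    expect_true(all(setdiff(cellIds(tp0$mesh1),
                            boundaryCells(tp0$mesh1)) %in% tm0$from))
})

test_that("a T1 transition swaps adjacency among exactly four cells", {
    mesh <- hexagonalMesh(5, 5)
    ie <- innerEdges(mesh)
    expect_gt(nrow(ie), 0)
    e <- ie[which.min(abs(ie$cellP - 13) + abs(ie$cellQ - 13))[1], ]
    pert <- applyT1(mesh, c(e$va, e$vb))
    s1 <- neighbourSets(mesh)
    s2 <- neighbourSets(pert)
    changed <- names(s1)[!mapply(identical, s1, s2[names(s1)])]
    expect_setequal(as.integer(changed),
                    c(e$cellP, e$cellQ, e$cellA, e$cellB))
    ## losing cells were 6-sided, now 5; gaining cells now 7
    f2 <- epimcs:::.frameData(pert)
    deg <- stats::setNames(f2$deg, f2$ids)
    expect_equal(unname(deg[as.character(c(e$cellP, e$cellQ))]), c(5L, 5L))
    expect_equal(unname(deg[as.character(c(e$cellA, e$cellB))]), c(7L, 7L))
    ## total network edge count unchanged (one removed, one added)
    expect_equal(igraph::ecount(cellNetwork(pert)),
                 igraph::ecount(cellNetwork(mesh)))
    ## the new edge has the requested length
    expect_error(applyT1(mesh, c(-1, -2)), "inner edge")
})

test_that("a T2 transition collapses a cell into a rosette vertex", {
    mesh <- generateTissue(7, 7, seed = 21)
    interior <- setdiff(cellIds(mesh), boundaryCells(mesh))
    f <- epimcs:::.frameData(mesh)
    victim <- interior[which.max(f$deg[match(interior, f$ids)])]
    nb <- neighbourSets(mesh)[[as.character(victim)]]
    pert <- applyT2(mesh, victim)
    expect_equal(nCells(pert), nCells(mesh) - 1L)
    expect_false(victim %in% cellIds(pert))
    ## all former neighbours share one vertex (the rosette centre)
    cells2 <- cellPolygons(pert)
    shared <- Reduce(intersect, cells2[as.character(nb)])
    expect_equal(length(shared), 1L)
    ## consecutive former neighbours stay adjacent: the rosette is a cycle
    net2 <- cellNetwork(pert)
    rosette <- igraph::induced_subgraph(net2, as.character(nb))
    expect_true(all(igraph::degree(rosette) == 2))
    expect_equal(igraph::ecount(rosette), length(nb))
    expect_error(applyT2(mesh, boundaryCells(mesh)[1]), "interior")
})

test_that("division bisects a cell and grows two cut neighbours", {
    set.seed(99)
    mesh <- generateTissue(7, 7, seed = 22)
    interior <- setdiff(cellIds(mesh), boundaryCells(mesh))
    ce <- cellCentroids(mesh)
    victim <- interior[which.min((ce[match(interior, cellIds(mesh)), 1] - 3.5)^2 +
                                 (ce[match(interior, cellIds(mesh)), 2] - 3.5)^2)]
    aMother <- cellAreas(mesh)[[as.character(victim)]]
    for (rep in 1:20) {
        dv <- tryCatch(applyDivision(mesh, victim),
                       notApplicableError = function(e) NULL)
        if (is.null(dv)) next
        rec <- dv$record
        expect_equal(nCells(dv$mesh), nCells(mesh) + 1L)
        aD <- cellAreas(dv$mesh)
        expect_equal(aD[[as.character(rec$daughter1)]] +
                     aD[[as.character(rec$daughter2)]], aMother)
        ## daughters are adjacent along the cleavage edge
        net <- cellNetwork(dv$mesh)
        expect_true(igraph::are_adjacent(net, as.character(rec$daughter1),
                                         as.character(rec$daughter2)))
        ## unless the cut snapped to a vertex, exactly the two cut cells
        ## gain an edge
        s1 <- neighbourSets(mesh)
        s2 <- neighbourSets(dv$mesh)
        common <- setdiff(names(s1), as.character(victim))
        gained <- common[vapply(common, function(id)
            length(setdiff(setdiff(s2[[id]], s1[[id]]),
                           c(rec$daughter1, rec$daughter2))) == 0 &&
            length(s2[[id]]) > length(s1[[id]]), logical(1))]
        nSides <- lengths(cellPolygons(dv$mesh)[as.character(
            c(rec$daughter1, rec$daughter2))])
        if (all(nSides > 3)) expect_equal(length(gained), 2L)
    }
})

test_that("perturbation operators keep meshes valid", {
    mesh <- generateTissue(6, 6, seed = 31)
    ie <- innerEdges(mesh)
    m1 <- applyT1(mesh, c(ie$va[1], ie$vb[1]))
    expect_true(validObject(m1))
    interior <- setdiff(cellIds(mesh), boundaryCells(mesh))
    m2 <- applyT2(mesh, interior[1])
    expect_true(validObject(m2))
    set.seed(1)
    m3 <- applyDivision(mesh, interior[2])$mesh
    expect_true(validObject(m3))
})

test_that("random T1 doses hit their target count", {
    set.seed(5)
    mesh <- generateTissue(10, 10, seed = 55)
    out <- applyRandomT1s(mesh, 0.05)
    expect_equal(out$nApplied, round(0.05 * out$nInner))
    ## affected cells ~ 4 per swap, reduced by overlap
    aff <- changedNeighbourFraction(mesh, out$mesh)
    expect_gte(aff * nCells(mesh), 2 * out$nApplied)
    expect_lte(aff * nCells(mesh), 4 * out$nApplied)
})
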