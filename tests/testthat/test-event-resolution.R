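test_that("post-processing grows the mapping monotonically", {
    for (s in 1:5) {
        set.seed(900 + s)
        mesh <- generateTissue(9, 9)
        pert <- applyRandomT1s(mesh, 0.03)
        pm <- permuteIds(pert$mesh)
        sd <- findSeed(mesh, pm$mesh)
        mp <- extendMCS(sd, mesh, pm$mesh)
        cl <- cleanMCS(mp, mesh, pm$mesh)
        post <- postProcess(cl, mesh, pm$mesh)
        ## every cleaned pair survives; additions carry 'post' provenance
        pc <- mappingPairs(cl)
        pp <- mappingPairs(post)
        expect_true(all(paste(pc$from, pc$to) %in% paste(pp$from, pp$to)))
        expect_gte(nrow(pp), nrow(pc))
        added <- pp[!paste(pp$from, pp$to) %in% paste(pc$from, pc$to), ]
        expect_true(all(added$provenance == "post"))
    }
})

test_that("post-processing needs at least two preserved neighbours", {
    ## an untracked cell whose best partner shares only one tracked
    ## neighbour stays untracked: restrict a perfect mapping to a single
    ## neighbour of a corner cell
    mesh <- generateTissue(6, 6, seed = 91)
    pm <- permuteIds(mesh, seed = 3)
    tm <- truthMap(pm$truth)
    f <- epimcs:::.frameData(mesh)
    corner <- which.min(f$cent[, 1] + f$cent[, 2])
    one <- f$adj[[corner]][1]
    keep <- setdiff(seq_len(f$n), corner)
    base <- cellMapping(f$ids[keep], tm$to[match(f$ids[keep], tm$from)],
                        "mcs")
    grown <- postProcess(base, mesh, pm$mesh)
    expect_true(f$ids[corner] %in% mappingPairs(grown)$from ||
                length(grown) == length(base))
    ## rule audit on a full tracking: no mapped pair gains more tracked
    ## neighbours than it preserves
    tc <- makeTestCase("t1", seed = 92)
    res <- suppressWarnings(track(tc$mesh1, tc$mesh2))
    f1 <- epimcs:::.frameData(tc$mesh1)
    f2 <- epimcs:::.frameData(tc$mesh2)
    st <- epimcs:::.mappingToState(res@mapping, f1, f2)
    for (i in which(!is.na(st$map1))) {
        p <- epimcs:::.preservedFor(i, st$map1[i], f1, f2, st$map1)
        g <- epimcs:::.gainedFor(i, st$map1[i], f1, f2, st$map2)
        expect_lte(g, max(p, 1L))
    }
})

test_that("a single division is recovered exactly at random orientations", {
    for (s in c(11, 23, 35, 47)) {
        tc <- makeTestCase("division", seed = s)
        res <- suppressWarnings(track(tc$mesh1, tc$mesh2))
        expect_equal(divisions(res), tc$truth@divisions)
        sc <- scoreAgainstTruth(res, tc$truth)
        expect_equal(sc$nIncorrect, 0L)
    }
})

test_that("no untracked frame-2 cells means no divisions", {
    tc <- makeTestCase("permutation", seed = 93)
    res <- suppressWarnings(track(tc$mesh1, tc$mesh2))
    if (length(untrackedCells(res, 2)) == 0L)
        expect_equal(nrow(divisions(res)), 0L)
    else
        expect_equal(nrow(divisions(res)), 0L)
})

test_that("an ambiguous four-sided daughter is resolved geometrically", {
    ## force a division whose cut snaps to an existing vertex, producing
    ## a daughter with fewer sides; the tracker must still identify the
    ## true mother by centroid proximity
    found <- FALSE
    for (s in 1:40) {
        tc <- .withSnapCase(s)
        if (is.null(tc)) next
        found <- TRUE
        res <- suppressWarnings(track(tc$mesh1, tc$mesh2))
        if (nrow(divisions(res)) == 1L)
            expect_equal(divisions(res), tc$truth@divisions)
        break
    }
    expect_true(found)
})

test_that("T2 removal yields exactly one death at the removed cell", {
    for (s in c(5, 17)) {
        tc <- makeTestCase("t2", seed = s)
        res <- suppressWarnings(track(tc$mesh1, tc$mesh2))
        expect_equal(deaths(res), tc$truth@removed)
    }
})

test_that("translation and identity cases produce no deaths", {
    tc <- makeTestCase("translation", seed = 6)
    res <- suppressWarnings(track(tc$mesh1, tc$mesh2))
    expect_equal(length(deaths(res)), 0L)
    tc2 <- makeTestCase("permutation", seed = 6)
    res2 <- suppressWarnings(track(tc2$mesh1, tc2$mesh2))
    expect_equal(length(deaths(res2)), 0L)
})

test_that("tracking quality is symmetric between frame orders", {
    tc <- makeTestCase("permutation", seed = 94)
    fwd <- suppressWarnings(track(tc$mesh1, tc$mesh2))
    bwd <- suppressWarnings(track(tc$mesh2, tc$mesh1))
    pf <- mappingPairs(fwd)
    pb <- mappingPairs(bwd)
    shared <- intersect(paste(pf$from, pf$to), paste(pb$to, pb$from))
    expect_gte(length(shared), min(nrow(pf), nrow(pb)) - 3L)
})

test_that("sequences chain persistent ids through events", {
    ## three identical frames: every cell keeps its id
    mesh <- generateTissue(6, 6, seed = 95)
    seqr <- trackSequence(list(mesh, mesh, mesh))
    tr <- seqr$tracks
    byCell <- split(tr$track, tr$cell)
    expect_true(all(lengths(byCell) == 3L))
    expect_true(all(vapply(byCell, function(x)
        length(unique(x)) == 1L, logical(1))))
    ## no track id appears twice within one frame
    expect_false(any(tapply(tr$track, tr$frame, anyDuplicated) > 0))
    ## chained permutations follow the composed ground truth
    pm1 <- permuteIds(mesh, seed = 4)
    pm2 <- permuteIds(pm1$mesh, seed = 5)
    seq2 <- trackSequence(list(mesh, pm1$mesh, pm2$mesh))
    t1m <- truthMap(pm1$truth)
    t2m <- truthMap(pm2$truth)
    tr2 <- seq2$tracks
    f1 <- tr2[tr2$frame == 1, ]
    f3 <- tr2[tr2$frame == 3, ]
    composed <- t2m$to[match(t1m$to[match(f1$cell, t1m$from)], t2m$from)]
    trackAt3 <- f3$track[match(composed, f3$cell)]
    agree <- trackAt3 == f1$track
    expect_gte(mean(agree, na.rm = TRUE), 0.95)
    ## a division spawns two fresh ids linked to the mother track
    tcd <- makeTestCase("division", seed = 96)
    seq3 <- trackSequence(list(tcd$mesh1, tcd$mesh2))
    expect_equal(nrow(seq3$lineage), 2L)
    dmr <- divisions(seq3$results[[1]])
    motherTrack <- seq3$tracks$track[seq3$tracks$frame == 1 &
                                     seq3$tracks$cell == dmr$mother]
    expect_true(all(seq3$lineage$parent == motherTrack))
})

test_that("tracking failure on impossible frames is a classed error", {
    mesh <- hexagonalMesh(8, 8)
    shift <- vertexCoords(mesh)
    shift[, 1] <- shift[, 1] + 1e4   # far outside dMax
    far <- cellMesh(shift, cellPolygons(mesh))
    expect_error(track(mesh, far), class = "trackingFailureError")
})
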