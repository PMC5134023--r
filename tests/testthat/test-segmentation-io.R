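test_that("four quadrant labels meeting centrally give one 4-fold junction", {
    img <- matrix(0L, 20, 20)
    img[3:10, 3:10] <- 1L
    img[3:10, 11:18] <- 2L
    img[11:18, 3:10] <- 3L
    img[11:18, 11:18] <- 4L
    ## all four cells touch background, so conversion must report a
    ## degenerate frame; the junction scan itself is checked directly
    expect_error(meshFromLabelImage(img), "interior",
                 class = "degenerateFrameError")
    ## junction detection: pad and scan by hand through the internal path
    ## of a 3x3 label block, which keeps one interior cell
    img2 <- matrix(0L, 32, 32)
    labs <- matrix(1:9, 3, 3)
    for (i in 1:3) for (j in 1:3)
        img2[(2 + (i - 1) * 9):(1 + i * 9 + ifelse(i == 3, 1, 0)),
             (2 + (j - 1) * 9):(1 + j * 9 + ifelse(j == 3, 1, 0))] <-
            labs[i, j]
    expect_error(meshFromLabelImage(img2), class = "degenerateFrameError")
})

test_that("rasterized synthetic tissue recovers its adjacency network", {
    mesh <- generateTissue(9, 9, seed = 61)
    img <- rasterizeMesh(mesh, pixelsPerUnit = 20)
    rec <- meshFromLabelImage(img)
    ## recovered interior cells keep their label ids; adjacency among
    ## cells interior in both meshes must agree exactly
    common <- intersect(cellIds(rec), cellIds(mesh))
    expect_gt(length(common), 0.4 * nCells(mesh))
    sRef <- neighbourSets(mesh)
    sRec <- neighbourSets(rec)
    inner <- setdiff(common, c(boundaryCells(rec)))
    expect_gt(length(inner), 10)
    ## shared-edge lengths of the source mesh, for classifying losses
    se <- epimcs:::.sharedEdges(mesh)
    se <- se[!is.na(se$cell2), ]
    v <- vertexCoords(mesh)
    len <- sqrt((v[as.character(se$va), 1] - v[as.character(se$vb), 1])^2 +
                (v[as.character(se$va), 2] - v[as.character(se$vb), 2])^2)
    pairLen <- tapply(len, paste(pmin(se$cell1, se$cell2),
                                 pmax(se$cell1, se$cell2)), sum)
    for (id in inner) {
        a <- intersect(sRec[[as.character(id)]], common)
        b <- intersect(sRef[[as.character(id)]], common)
        ## no adjacency invented by the conversion
        expect_true(all(a %in% b))
        ## adjacency is only lost for contacts below the short-edge
        ## threshold (2 px), which the conversion merges by design
        lost <- setdiff(b, a)
        if (length(lost)) {
            k <- paste(pmin(id, lost), pmax(id, lost))
            expect_true(all(pairLen[k] * 20 < 3))
        }
    }
})

test_that("conversion is invariant to label permutation", {
    mesh <- generateTissue(7, 7, seed = 62)
    img <- rasterizeMesh(mesh, pixelsPerUnit = 15)
    labs <- sort(unique(as.integer(img[img > 0])))
    perm <- stats::setNames(sample(seq_along(labs) + 1000L), labs)
    img2 <- img
    img2[img > 0] <- perm[as.character(img[img > 0])]
    m1 <- meshFromLabelImage(img)
    m2 <- meshFromLabelImage(img2)
    expect_equal(nCells(m1), nCells(m2))
    s1 <- neighbourSets(m1)
    s2 <- neighbourSets(m2)
    for (id in cellIds(m1)) {
        expect_setequal(unname(perm[as.character(s1[[as.character(id)]])]),
                        s2[[as.character(perm[as.character(id)])]])
    }
})

test_that("short-edge removal only affects sub-threshold contacts", {
    mesh <- generateTissue(7, 7, seed = 63)
    img <- rasterizeMesh(mesh, pixelsPerUnit = 15)
    loose <- meshFromLabelImage(img, minEdgePx = 0)
    merged <- meshFromLabelImage(img, minEdgePx = 3)
    common <- intersect(cellIds(loose), cellIds(merged))
    sL <- neighbourSets(loose)
    sM <- neighbourSets(merged)
    ## shared-edge lengths in the unmerged mesh, per cell pair
    se <- epimcs:::.sharedEdges(loose)
    se <- se[!is.na(se$cell2), ]
    v <- vertexCoords(loose)
    len <- sqrt((v[as.character(se$va), 1] - v[as.character(se$vb), 1])^2 +
                (v[as.character(se$va), 2] - v[as.character(se$vb), 2])^2)
    pairLen <- tapply(len, paste(pmin(se$cell1, se$cell2),
                                 pmax(se$cell1, se$cell2)), sum)
    inner <- setdiff(common, union(boundaryCells(loose),
                                   boundaryCells(merged)))
    for (id in inner) {
        a <- intersect(sL[[as.character(id)]], common)
        b <- intersect(sM[[as.character(id)]], common)
        ## merging may only remove adjacencies, never invent them
        expect_true(all(b %in% a))
        ## and any removed adjacency was a sub-threshold contact
        lost <- setdiff(a, b)
        if (length(lost)) {
            k <- paste(pmin(id, lost), pmax(id, lost))
            expect_true(all(pairLen[k] < 3))
        }
    }
    ## merging really removed short edges
    nv <- function(m) nrow(vertexCoords(m))
    expect_lt(nv(merged), nv(loose))
})

test_that("label images round-trip through 16-bit TIFF", {
    img <- matrix(sample(c(0:5, 40000L), 100, replace = TRUE), 10, 10)
    path <- tempfile(fileext = ".tif")
    writeLabelImage(img, path)
    expect_equal(readLabelImage(path), img, ignore_attr = TRUE)
    expect_error(writeLabelImage(img, tempfile(fileext = ".png")),
                 "16-bit TIFF")
})

test_that("tracking tables round-trip losslessly", {
    ## empty mapping: header-only file
    empty <- epimcs:::.trackingResult(cellMapping())
    path <- tempfile(fileext = ".tsv")
    writeTracking(empty, path)
    expect_equal(length(readLines(path)), 1L)
    expect_equal(length(trackedMapping(readTracking(path))), 0L)
    ## small mapping with a death
    res <- epimcs:::.trackingResult(
        cellMapping(c(1L, 2L), c(4L, 7L), c("seed", "post")),
        deaths = 9L, untracked1 = 5L, untracked2 = 11L)
    writeTracking(res, path)
    back <- readTracking(path)
    expect_equal(mappingPairs(back), mappingPairs(res))
    expect_equal(deaths(back), deaths(res))
    expect_equal(untrackedCells(back, 1), untrackedCells(res, 1))
    expect_equal(untrackedCells(back, 2), untrackedCells(res, 2))
    ## full tracker output (permutation test case) round-trips
    tc <- makeTestCase("division", seed = 3)
    res2 <- suppressWarnings(track(tc$mesh1, tc$mesh2))
    writeTracking(res2, path)
    back2 <- readTracking(path)
    expect_equal(mappingPairs(back2)[order(mappingPairs(back2)$from), ],
                 mappingPairs(res2)[order(mappingPairs(res2)$from), ],
                 ignore_attr = TRUE)
    expect_equal(divisions(back2), divisions(res2), ignore_attr = TRUE)
    ## malformed table reports a parse problem
    writeLines(c("frame\tcell_id\ttrack_id\tevent", "3\t1\t1\tmcs"), path)
    expect_error(readTracking(path), "bad frame at line 2")
})
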