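test_that("dual network matches a brute-force shared-edge scan", {
    mesh <- generateTissue(9, 9, seed = 101)
    net <- cellNetwork(mesh)
    expect_setequal(igraph::V(net)$name, as.character(cellIds(mesh)))
    expect_equal(edgesOfGraph(net), bruteForceAdjacency(mesh),
                 ignore_attr = TRUE)
})

test_that("single isolated cell gives a one-node, zero-edge network", {
    vs <- data.frame(id = 1:4, x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
    m <- cellMesh(vs, list(`7` = 1:4))
    net <- cellNetwork(m)
    expect_equal(igraph::vcount(net), 1L)
    expect_equal(igraph::ecount(net), 0L)
    expect_equal(boundaryCells(m), 7L)
})

test_that("hexagonal lattice interior cells have degree six", {
    mesh <- hexagonalMesh(5, 5)
    net <- cellNetwork(mesh)
    interior <- setdiff(cellIds(mesh), boundaryCells(mesh))
    expect_true(length(interior) >= 1)
    expect_true(all(igraph::degree(net, as.character(interior)) == 6))
    ## interior degree equals polygon side count
    expect_true(all(lengths(cellPolygons(mesh)[as.character(interior)])
                    == 6))
})

test_that("degree sum equals twice the edge count", {
    for (s in 1:3) {
        mesh <- generateTissue(6, 6, seed = 200 + s)
        net <- cellNetwork(mesh)
        expect_equal(sum(igraph::degree(net)), 2L * igraph::ecount(net))
    }
})

test_that("network building is invariant to cell insertion order", {
    mesh <- generateTissue(5, 5, seed = 77)
    cells <- cellPolygons(mesh)
    perm <- rev(seq_along(cells))
    mesh2 <- cellMesh(vertexCoords(mesh), cells[perm])
    expect_equal(edgesOfGraph(cellNetwork(mesh)),
                 edgesOfGraph(cellNetwork(mesh2)))
})

test_that("neighbourhood graphs agree with breadth-first search", {
    mesh <- generateTissue(7, 7, seed = 33)
    net <- cellNetwork(mesh)
    interior <- setdiff(cellIds(mesh), boundaryCells(mesh))
    for (cell in interior[c(1, length(interior) %/% 2, length(interior))]) {
        for (ord in 1:2) {
            sub <- neighbourhoodGraph(net, cell, order = ord)
            bfs <- igraph::ego(net, order = ord,
                               nodes = as.character(cell))[[1]]
            expect_setequal(igraph::V(sub)$name, names(bfs))
            expect_equal(sum(igraph::V(sub)$centre), 1L)
        }
    }
    expect_error(neighbourhoodGraph(net, max(cellIds(mesh)) + 1000L),
                 "unknown cell")
})

test_that("hexagonal interior neighbourhood counts match lattice theory", {
    mesh <- hexagonalMesh(7, 7)
    net <- cellNetwork(mesh)
    ## a cell two rings away from the lattice edge
    f <- epimcs:::.frameData(mesh)
    deep <- f$ids[!f$nbhd2TouchesBoundary][1]
    expect_equal(igraph::vcount(neighbourhoodGraph(net, deep, 1)), 7L)
    expect_equal(igraph::vcount(neighbourhoodGraph(net, deep, 2)), 19L)
})

test_that("boundary cells of a 3x3 grid are the rim", {
    mesh <- rectangularMesh(3, 3)
    expect_equal(boundaryCells(mesh), setdiff(1:9, 5L))
    mesh2 <- generateTissue(9, 9, seed = 5)
    ## oracle: cells owning an edge not shared with any other cell
    ed <- epimcs:::.sharedEdges(mesh2)
    expect_equal(boundaryCells(mesh2),
                 sort(unique(ed$cell1[is.na(ed$cell2)])))
})

test_that("mean cell length is sqrt of mean area", {
    mesh <- generateTissue(5, 5, seed = 9)
    expect_equal(meanCellLength(mesh), sqrt(mean(cellAreas(mesh))))
})

test_that("a mesh with an edge shared by three cells is invalid", {
    vs <- data.frame(id = 1:5, x = c(0, 1, 1, 0, 2), y = c(0, 0, 1, 1, 0.5))
    expect_error(
        cellMesh(vs, list(`1` = c(1, 2, 3, 4), `2` = c(2, 5, 3),
                          `3` = c(2, 3, 5))),
        "more than 2 cells")
})

test_that("mesh JSON serialization round-trips", {
    mesh <- generateTissue(5, 5, seed = 4)
    path <- tempfile(fileext = ".json")
    writeCellMesh(mesh, path)
    back <- readCellMesh(path)
    expect_equal(cellPolygons(back), cellPolygons(mesh))
    expect_equal(vertexCoords(back), vertexCoords(mesh))
})
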