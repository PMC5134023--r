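#' @include tissue-mesh.R
NULL

.degenerateFrame <- function(msg) {
    structure(class = c("degenerateFrameError", "error", "condition"),
              list(message = msg, call = sys.call(-1)))
}

#' Read a 16-bit label image
#'
#' Reads a segmented frame stored as TIFF or PNG, in which the pixels of
#' each cell carry one positive integer label (the convention of common
#' watershed-based segmentation tools). PNG intensities are rescaled back
#' to the 16-bit integer range.
#'
#' @param path path to a `.tif`/`.tiff` or `.png` file
#' @return an integer matrix (rows = image rows)
#' @export
readLabelImage <- function(path) {
    lower <- tolower(path)
    if (grepl("\\.tiff?$", lower)) {
        img <- tiff::readTIFF(path, as.is = TRUE)
    } else if (grepl("\\.png$", lower)) {
        img <- round(png::readPNG(path) * 65535)
    } else stop("unsupported label-image format: ", path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    storage.mode(img) <- "integer"
    img
}

#' @param img integer matrix of labels
#' @rdname readLabelImage
#' @details `writeLabelImage()` writes 16-bit TIFF only; 16-bit PNGs (for
#'   example from pixel-classification tools) can be read but not written,
#'   since the PNG writer available to R stores 8 bits per channel.
#' @export
writeLabelImage <- function(img, path) {
    if (!grepl("\\.tiff?$", tolower(path)))
        stop("label images are written as 16-bit TIFF; got: ", path)
    tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L)
    invisible(path)
}

#' Convert a label image to a polygonal mesh
#'
#' Junctions where three or more cells meet are detected with a 2x2
#' pixel-window scan: a vertex is placed at the centre of every window
#' containing at least three distinct labels (the background counts as a
#' label, so junctions on the tissue boundary are found too). Vertices are
#' assigned to the cells present in their window and ordered by angle
#' around each cell's pixel centroid. Polygon edges shorter than
#' `minEdgePx` are then removed and replaced by a single vertex at the
#' edge midpoint, and finally the polygons on the tissue boundary
#' (adjacent to background or to the image edge) are dropped, since their
#' shapes are poorly approximated by polygons.
#'
#' Pixel coordinates follow the image convention: origin at the top-left,
#' x along columns, y along rows; window-centre vertices have half-integer
#' coordinates.
#'
#' @param img integer label matrix, as from [readLabelImage()]
#' @param minEdgePx minimum polygon edge length in pixels
#' @param backgroundLabel label value of the background/membrane class
#'   (0 for typical pixel-classification exports)
#' @return a [CellMesh-class] of the interior cells
#' @export
meshFromLabelImage <- function(img, minEdgePx = 2, backgroundLabel = 0L) {
    stopifnot(is.matrix(img))
    bg <- as.integer(backgroundLabel)
    pad <- matrix(bg, nrow(img) + 2L, ncol(img) + 2L)
    pad[2:(nrow(img) + 1L), 2:(ncol(img) + 1L)] <- img
    nr <- nrow(pad); nc <- ncol(pad)
    ## 2x2 windows: count distinct labels among the four pixels
    a <- pad[-nr, -nc]; b <- pad[-nr, -1L]; c2 <- pad[-1L, -nc]
    d <- pad[-1L, -1L]
    distinct <- 1L + (b != a) + (c2 != a & c2 != b) +
        (d != a & d != b & d != c2)
    jw <- which(distinct >= 3L, arr.ind = TRUE)
    if (!nrow(jw)) stop(.degenerateFrame("no three-cell junctions found"))
    ## vertex coordinates in original-image pixel units (origin top-left):
    ## window over padded cols (c, c+1) has centre c + 0.5, which is
    ## c - 0.5 after removing the one-pixel pad
    vx <- jw[, 2L] - 0.5
    vy <- jw[, 1L] - 0.5
    nVert <- nrow(jw)
    winLabels <- cbind(a[jw], b[jw], c2[jw], d[jw])
    ## cell -> vertices incidence
    inc <- data.frame(vert = rep(seq_len(nVert), 4L),
                      lab = as.integer(winLabels))
    inc <- unique(inc[inc$lab != bg, ])
    labels <- sort(unique(as.integer(img[img != bg])))
    ## pixel centroids per label
    pos <- which(img != bg, arr.ind = TRUE)
    labAt <- img[pos]
    cy <- tapply(pos[, 1L], labAt, mean)
    cx <- tapply(pos[, 2L], labAt, mean)
    cells <- lapply(labels, function(L) {
        vs <- inc$vert[inc$lab == L]
        if (length(vs) < 3L) return(NULL)
        ang <- atan2(vy[vs] - cy[as.character(L)],
                     vx[vs] - cx[as.character(L)])
        vs[order(ang)]
    })
    names(cells) <- labels
    empty <- vapply(cells, is.null, logical(1))
    cells <- cells[!empty]
    labels <- labels[!empty]
    verts <- cbind(x = vx, y = vy)
    rownames(verts) <- seq_len(nVert)
    ## short-edge removal: merge the two endpoints into a midpoint vertex
    repeat {
        edges <- do.call(rbind, lapply(cells, function(ids)
            cbind(ids, c(ids[-1L], ids[1L]))))
        len <- sqrt((verts[edges[, 1L], 1L] - verts[edges[, 2L], 1L])^2 +
                    (verts[edges[, 1L], 2L] - verts[edges[, 2L], 2L])^2)
        short <- which(len > 0 & len < minEdgePx)
        if (!length(short)) break
        k <- short[which.min(len[short])]
        u <- edges[k, 1L]; w <- edges[k, 2L]
        mid <- (verts[u, ] + verts[w, ]) / 2
        newId <- nrow(verts) + 1L
        verts <- rbind(verts, mid)
        rownames(verts)[newId] <- newId
        cells <- lapply(cells, function(ids) {
            ids[ids %in% c(u, w)] <- newId
            ids[ids != c(ids[-1L], ids[1L])]
        })
        bad <- lengths(cells) < 3L
        cells <- cells[!bad]
    }
    ## boundary cells: any 4-neighbourhood contact with background
    touchBg <- (pad[-c(nr - 1L, nr), -c(1L, nc)] == bg |
                pad[-c(1L, 2L), -c(1L, nc)] == bg |
                pad[-c(1L, nr), -c(nc - 1L, nc)] == bg |
                pad[-c(1L, nr), -c(1L, 2L)] == bg) & img != bg
    bndLabels <- unique(as.integer(img[touchBg]))
    keep <- !(as.integer(names(cells)) %in% bndLabels)
    cells <- cells[keep]
    if (length(cells) < 3L)
        stop(.degenerateFrame(
            "fewer than 3 interior cells in the label image"))
    used <- sort(unique(unlist(cells)))
    verts <- verts[used, , drop = FALSE]
    cellMesh(verts, cells)
}

#' Rasterize a mesh into a label image
#'
#' Renders each cell polygon into a synthetic 16-bit label image (cell id
#' as pixel value, `0` background). Useful for round-trip validation of
#' the label-image conversion and for exporting synthetic tissues in the
#' format produced by segmentation tools.
#'
#' @param mesh a [CellMesh-class]
#' @param pixelsPerUnit raster resolution
#' @param pad background margin in pixels
#' @return an integer label matrix
#' @export
rasterizeMesh <- function(mesh, pixelsPerUnit = 20, pad = 3L) {
    v <- mesh@vertices
    s <- pixelsPerUnit
    x0 <- min(v[, 1]); y0 <- min(v[, 2])
    w <- ceiling((max(v[, 1]) - x0) * s) + 2L * pad
    h <- ceiling((max(v[, 2]) - y0) * s) + 2L * pad
    img <- matrix(0L, h, w)
    ids <- sort(as.integer(names(mesh@cells)))
    for (id in ids) {
        p <- v[as.character(mesh@cells[[as.character(id)]]), , drop = FALSE]
        px <- (p[, 1] - x0) * s + pad
        py <- (p[, 2] - y0) * s + pad
        cr <- max(1L, floor(min(px))):min(w, ceiling(max(px)))
        rr <- max(1L, floor(min(py))):min(h, ceiling(max(py)))
        grid <- expand.grid(r = rr, c = cr)
        inside <- .pointsInPolygon(grid$c - 0.5, grid$r - 0.5,
                                   cbind(px, py))
        sel <- grid[inside, , drop = FALSE]
        free <- img[cbind(sel$r, sel$c)] == 0L
        img[cbind(sel$r[free], sel$c[free])] <- id
    }
    img
}

## ---------------------------------------------------------------------------
## tracking tables
## ---------------------------------------------------------------------------

#' Write and read tracking results as tab-separated tables
#'
#' Serializes a [TrackingResult-class] to a TSV file with columns `frame`,
#' `cell_id`, `track_id` and `event`, and reads it back losslessly
#' (mapping with provenance, divisions, deaths and untracked cells).
#'
#' @param result a [TrackingResult-class]
#' @param path file path
#' @return `readTracking()` returns a `TrackingResult`; `writeTracking()`
#'   returns `path` invisibly.
#' @export
writeTracking <- function(result, path) {
    p <- result@mapping@pairs
    rows <- data.frame(frame = integer(), cell_id = integer(),
                       track_id = integer(), event = character())
    if (nrow(p)) {
        o <- order(p$from)
        rows <- rbind(rows,
            data.frame(frame = 1L, cell_id = p$from[o],
                       track_id = seq_len(nrow(p)), event = p$provenance[o]),
            data.frame(frame = 2L, cell_id = p$to[o],
                       track_id = seq_len(nrow(p)), event = p$provenance[o]))
    }
    d <- result@divisions
    for (j in seq_len(nrow(d))) {
        rows <- rbind(rows,
            data.frame(frame = 1L, cell_id = d$mother[j], track_id = NA,
                       event = "division"),
            data.frame(frame = 2L,
                       cell_id = c(d$daughter1[j], d$daughter2[j]),
                       track_id = NA,
                       event = sprintf("daughter:%d", d$mother[j])))
    }
    if (length(result@deaths))
        rows <- rbind(rows, data.frame(frame = 1L, cell_id = result@deaths,
                                       track_id = NA, event = "death"))
    if (length(result@untracked1))
        rows <- rbind(rows, data.frame(frame = 1L,
                                       cell_id = sort(result@untracked1),
                                       track_id = NA, event = "untracked"))
    if (length(result@untracked2))
        rows <- rbind(rows, data.frame(frame = 2L,
                                       cell_id = sort(result@untracked2),
                                       track_id = NA, event = "untracked"))
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeTracking
#' @export
readTracking <- function(path) {
    tab <- tryCatch(
        utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("integer", "integer", "integer",
                                         "character")),
        error = function(e) stop("malformed tracking table '", path, "': ",
                                 conditionMessage(e), call. = FALSE))
    need <- c("frame", "cell_id", "track_id", "event")
    if (!identical(names(tab), need))
        stop("malformed tracking table '", path,
             "': expected columns ", paste(need, collapse = ", "))
    bad <- which(!tab$frame %in% c(1L, 2L))
    if (length(bad))
        stop("malformed tracking table '", path, "': bad frame at line ",
             bad[1L] + 1L)
    mapRows <- tab[!is.na(tab$track_id), ]
    f1 <- mapRows[mapRows$frame == 1L, ]
    f2 <- mapRows[mapRows$frame == 2L, ]
    f2 <- f2[match(f1$track_id, f2$track_id), ]
    mapping <- cellMapping(f1$cell_id, f2$cell_id, f1$event)
    dau <- tab[grepl("^daughter:", tab$event), ]
    div <- data.frame(mother = integer(), daughter1 = integer(),
                      daughter2 = integer())
    if (nrow(dau)) {
        mo <- as.integer(sub("^daughter:", "", dau$event))
        for (m in unique(mo)) {
            ds <- sort(dau$cell_id[mo == m])
            if (length(ds) != 2L)
                stop("malformed tracking table '", path,
                     "': division of cell ", m, " needs two daughters")
            div <- rbind(div, data.frame(mother = m, daughter1 = ds[1L],
                                         daughter2 = ds[2L]))
        }
    }
    .trackingResult(mapping, div,
                    deaths = tab$cell_id[tab$event == "death"],
                    untracked1 = tab$cell_id[tab$event == "untracked" &
                                             tab$frame == 1L],
                    untracked2 = tab$cell_id[tab$event == "untracked" &
                                             tab$frame == 2L])
}
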