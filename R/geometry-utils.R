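## Internal planar-geometry helpers. All polygons are matrices with columns
## x, y and vertices in order; the shoelace sign convention is CCW > 0.

.polygonSignedArea <- function(p) {
    n <- nrow(p)
    if (n < 3L) return(0)
    j <- c(2:n, 1L)
    sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2]) / 2
}

.polygonArea <- function(p) abs(.polygonSignedArea(p))

.polygonCentroid <- function(p) {
    n <- nrow(p)
    j <- c(2:n, 1L)
    cr <- p[, 1] * p[j, 2] - p[j, 1] * p[, 2]
    a <- sum(cr) / 2
    if (abs(a) < 1e-12) return(colMeans(p))
    c(sum((p[, 1] + p[j, 1]) * cr), sum((p[, 2] + p[j, 2]) * cr)) / (6 * a)
}

## do open segments (p1,p2) and (p3,p4) properly intersect?
.segmentsCross <- function(p1, p2, p3, p4) {
    d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
        (b[2] - a[2]) * (c[1] - a[1])
    d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
    d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
    ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
        ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

## intersection parameter of segment a->b with infinite line through o with
## unit direction u (line given as points with u rotated normal); returns
## t in [0,1] along the segment, or NA if parallel / outside
.segmentLineIntersection <- function(a, b, o, dir) {
    nrm <- c(-dir[2], dir[1])
    da <- sum((a - o) * nrm)
    db <- sum((b - o) * nrm)
    if ((da > 0 && db > 0) || (da < 0 && db < 0)) return(NA_real_)
    if (da == db) return(NA_real_)
    da / (da - db)
}

## point-in-polygon (ray casting), vectorised over query points
.pointsInPolygon <- function(px, py, poly) {
    n <- nrow(poly)
    inside <- rep(FALSE, length(px))
    j <- n
    for (i in seq_len(n)) {
        xi <- poly[i, 1]; yi <- poly[i, 2]
        xj <- poly[j, 1]; yj <- poly[j, 2]
        crosses <- ((yi > py) != (yj > py)) &
            (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
        inside <- xor(inside, crosses)
        j <- i
    }
    inside
}
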