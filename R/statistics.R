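#' @include event-resolution.R
NULL

#' Score a tracking result against a known ground truth
#'
#' Classifies every cell in the ground-truth map's domain as correctly
#' tracked (mapped to its true partner), incorrectly tracked (mapped to
#' any other cell) or untracked, and returns the three fractions (which
#' sum to one).
#'
#' @param result a [TrackingResult-class]
#' @param truth a [GroundTruth-class] covering the frame-1 cells
#' @return one-row data.frame with columns `fractionCorrect`,
#'   `fractionIncorrect`, `fractionUntracked`, `nCells`, `nCorrect`,
#'   `nIncorrect`
#' @export
scoreAgainstTruth <- function(result, truth) {
    tm <- truth@map
    p <- result@mapping@pairs
    got <- p$to[match(tm$from, p$from)]
    correct <- !is.na(got) & got == tm$to
    incorrect <- !is.na(got) & got != tm$to
    n <- nrow(tm)
    data.frame(fractionCorrect = sum(correct) / n,
               fractionIncorrect = sum(incorrect) / n,
               fractionUntracked = sum(is.na(got)) / n,
               nCells = n, nCorrect = sum(correct),
               nIncorrect = sum(incorrect))
}

#' Fraction of cells whose neighbour relations changed
#'
#' Compares the neighbour id sets of the cells shared by two meshes (for
#' perturbed copies of a tissue this is a by-id comparison) and returns
#' the fraction of the reference mesh's cells whose neighbour set differs
#' or that are absent from the second mesh. This is the "affected cells"
#' measure used when quantifying how many cells a given dose of T1
#' transitions touches.
#'
#' @param meshRef,meshPert reference and perturbed [CellMesh-class]
#' @return a single numeric fraction
#' @export
changedNeighbourFraction <- function(meshRef, meshPert) {
    f1 <- .frameData(meshRef)
    f2 <- .frameData(meshPert)
    changed <- vapply(seq_len(f1$n), function(i) {
        j <- match(f1$ids[i], f2$ids)
        if (is.na(j)) return(TRUE)
        !identical(sort(f1$ids[f1$adj[[i]]]), sort(f2$ids[f2$adj[[j]]]))
    }, logical(1))
    mean(changed)
}

#' Tracking success as a function of the neighbour-exchange rate
#'
#' For each requested fraction of inner edges, generates `reps` fresh
#' tissues, applies T1 transitions to that fraction of their inner edges
#' ([applyRandomT1s()]), shuffles the ids of the perturbed copy, runs the
#' tracker and scores it against the ground truth. A run on which no seed
#' can be found (possible at extreme rearrangement rates, when every
#' neighbourhood changes) is recorded as fully untracked.
#'
#' @param fractions numeric vector of inner-edge fractions
#' @param reps tissues per fraction
#' @param m,n tissue dimensions in cells
#' @param config a [TrackerConfig-class]
#' @param seed integer; run `r` at fraction index `k` uses the seed
#'   `seed + 1000 * k + r`, so the whole sweep is reproducible
#' @return data.frame with one row per run: `fraction`, `rep`, `nCells`,
#'   `nApplied`, `nInner`, `affectedFraction` and the three score columns
#'   of [scoreAgainstTruth()]
#' @export
t1Sweep <- function(fractions = seq(0.01, 0.10, by = 0.01), reps = 10,
                    m = 20, n = 20, config = trackerConfig(), seed = 1) {
    out <- NULL
    for (k in seq_along(fractions)) {
        for (r in seq_len(reps)) {
            row <- .withSeed(seed + 1000L * k + r, {
                mesh1 <- generateTissue(m, n)
                pert <- applyRandomT1s(mesh1, fractions[k])
                aff <- changedNeighbourFraction(mesh1, pert$mesh)
                pm <- permuteIds(pert$mesh)
                res <- tryCatch(track(mesh1, pm$mesh, config),
                                trackingFailureError = function(e) NULL)
                sc <- if (is.null(res)) {
                    data.frame(fractionCorrect = 0, fractionIncorrect = 0,
                               fractionUntracked = 1,
                               nCells = nCells(mesh1), nCorrect = 0L,
                               nIncorrect = 0L)
                } else scoreAgainstTruth(res, pm$truth)
                cbind(data.frame(fraction = fractions[k], rep = r,
                                 nCells = nCells(mesh1),
                                 nApplied = pert$nApplied,
                                 nInner = pert$nInner,
                                 affectedFraction = aff), sc[, -4L])
            })
            out <- rbind(out, row)
        }
    }
    out
}

#' Per-frame summary statistics of a tracked sequence
#'
#' Computes, for each frame of a sequence tracked with [trackSequence()],
#' the cell count, mean cell area, number of tracked cells (towards the
#' next frame), number of rearranging cells (tracked cells whose neighbour
#' count changes between the frame and the next), and the division and
#' death counts.
#'
#' @param seqResult the list returned by [trackSequence()]
#' @param meshes the list of meshes that was tracked
#' @return data.frame with one row per frame
#' @export
frameStats <- function(seqResult, meshes) {
    K <- length(meshes)
    out <- data.frame(frame = seq_len(K),
                      nCells = vapply(meshes, nCells, integer(1)),
                      meanCellArea = vapply(meshes, function(m)
                          mean(cellAreas(m)), numeric(1)),
                      nTracked = NA_integer_, nRearranging = NA_integer_,
                      nDivisions = NA_integer_, nDeaths = NA_integer_)
    for (k in seq_len(K - 1L)) {
        res <- seqResult$results[[k]]
        f1 <- .frameData(meshes[[k]])
        f2 <- .frameData(meshes[[k + 1L]])
        p <- res@mapping@pairs
        d1 <- f1$deg[match(p$from, f1$ids)]
        d2 <- f2$deg[match(p$to, f2$ids)]
        out$nTracked[k] <- nrow(p)
        out$nRearranging[k] <- sum(d1 != d2)
        out$nDivisions[k] <- nrow(res@divisions)
        out$nDeaths[k] <- length(res@deaths)
    }
    out
}

#' Apical-area excursion of each track
#'
#' For every persistent track covering at least two frames, returns the
#' ratio of the maximal to the minimal cell area observed along the track.
#' Averaged over tracks this quantifies mitotic rounding: cells typically
#' enlarge their apical surface before dividing.
#'
#' @param seqResult the list returned by [trackSequence()]
#' @param meshes the list of meshes that was tracked
#' @return data.frame with columns `track`, `nFrames`, `areaRatio`
#' @export
trackAreaRatios <- function(seqResult, meshes) {
    tr <- seqResult$tracks
    areas <- numeric(0)
    key <- character(0)
    for (k in seq_along(meshes)) {
        a <- cellAreas(meshes[[k]])
        ids <- cellIds(meshes[[k]])
        rows <- tr[tr$frame == k, ]
        areas <- c(areas, a[match(rows$cell, ids)])
        key <- c(key, as.character(rows$track))
    }
    sp <- split(areas, key)
    sp <- sp[lengths(sp) >= 2L]
    data.frame(track = as.integer(names(sp)),
               nFrames = lengths(sp),
               areaRatio = vapply(sp, function(x) max(x) / min(x),
                                  numeric(1)),
               row.names = NULL)
}
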