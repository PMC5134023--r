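---
title: "Tracking epithelial cells by maximum common subgraphs: models and methods"
author: "epimcs authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking epithelial cells by maximum common subgraphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimcs)
```

## The problem

Live imaging of epithelial sheets produces sequences of segmented frames
in which each cell is a labelled region. Registering cells between
consecutive frames — tracking — must survive cell movement, neighbour
exchanges (T1 transitions), cell removal (T2 transitions, delamination,
death) and cell division, often at low temporal resolution where cells
move by large fractions of their diameter between frames. Methods that
match cells by position or shape degrade quickly in that regime.

`epimcs` instead matches *connectivity*. Each frame is reduced to a
polygonal tessellation (a `CellMesh`: vertices at junctions where three
or more cells meet, one simple polygon per cell) and to its dual
adjacency network (`cellNetwork()`: one node per cell, an edge whenever
two polygons share an edge). Cells are tracked by aligning the two
networks through a maximum common subgraph (MCS): the largest connected
network contained in both frames. Most cells do not rearrange between
frames, so the MCS covers the stable bulk of the tissue; the remaining
cells are inferred from their connections to already-tracked cells.

## The tracking pipeline

`track(mesh1, mesh2)` runs five stages.

**1. Seeding.** Exact MCS construction is NP-hard in general, but cell
networks are planar and locally sparse, which makes a seed-and-extend
strategy effective. The seed is a pair of cells whose second-order
neighbourhood networks (the cell, its neighbours, and their neighbours)
are isomorphic, with the centre cells anchored and centroids within the
displacement cutoff. If no such pair exists, a first-order neighbourhood
match is accepted, restricted to cells whose neighbourhood stays clear of
the tissue boundary (small boundary neighbourhoods match each other too
easily to be trusted).

Two refinements matter in nearly-homogeneous tissue, where many
neighbourhoods look alike. First, candidate cells are scanned in order of
increasing number of structure-compatible partners, so that cells with
*rare* neighbourhood signatures — which are far more informative — seed
first, and a cell with a unique isomorphic partner is preferred over an
ambiguous one. Second, seeding is repeated: if the seed pair does not
itself survive the later cleaning stage, or if the cleaned mapping's
displacement field is not locally smooth (see below), the seed was
spurious and the next candidate is tried.

**2. Iterative extension.** The untracked cell adjacent to the current
subgraph with the fewest potential matches is selected; its candidates
are second-frame cells with the same neighbour count that preserve the
connections to already-tracked cells and lie within the cutoff. Each
candidate is scored by the size of the exact *local* MCS between the two
cells' second-order neighbourhood graphs, anchored at the candidate pair
and constrained to agree with the global mapping so far. The best
candidate is accepted only when this local MCS accounts for the cell's
complete first-order neighbourhood; otherwise the cell is set aside — the
locally optimal choice is to exclude it, as happens around removal and
division sites — and may be revisited once more of its neighbours are
tracked. When no adjacent cell extends the subgraph, the seeding
procedure is re-run among the untracked cells before giving up.

The local MCS is computed by an exact branch-and-bound over common
connected induced subgraphs (`localMCS()`, implemented in C++). Working
on neighbourhood graphs of at most a few dozen nodes is the key
complexity reduction: globally the construction behaves subquadratically
in tissue size (verified by the scaling test) even though MCS itself is
exponential in the worst case.

**3. Cleaning.** Cells whose pairing is supported by fewer than
`minConnections` (default 3) tracked neighbours with preserved adjacency
in both frames are removed, and connected components of the
preserved-adjacency subgraph smaller than `minClusterSize` (default 11)
cells are discarded. Mismatches concentrate exactly where connectivity
carries little information, so cleaning trades a small amount of coverage
for near-zero error.

**4. Post-processing.** Untracked pairs are added greedily, most
preserved tracked-neighbour connections first, subject to three rules: at
least `postMinNeighbours` (default 2) preserved connections; a cell may
not gain more tracked neighbours between the frames than it preserves;
and the displacement cutoff. Pairs are only ever added, so coverage
grows monotonically from the cleaned MCS. This stage recovers the cells
adjacent to T1, removal and division sites that extension deliberately
skipped.

**5. Event resolution.** After post-processing, each division leaves a
cluster of untracked second-frame cells in the interior of the tracked
region. The cells adjacent to the cluster that gained an edge pin down
the division: mother and daughters are their shared neighbours. When one
daughter is three- or four-sided the network evidence is ambiguous and
the geometrically closest mother/daughter combination wins (smallest sum
of mother-to-daughter centroid distances — the only point where geometry
beyond centroids-for-tie-breaks enters). Clusters touching the tissue
boundary are cells entering the field of view, not divisions, and are
left untracked. Unresolvable configurations (for example adjacent
simultaneous divisions) produce a warning rather than a silent guess.
Deaths are untracked first-frame cells all of whose neighbours are
tracked and that do not lie on the tissue boundary.

## Planar orientation and displacement coherence

Two safeguards in this implementation deserve explanation because they go
beyond pure graph topology, and both exploit physics rather than
positions.

*Cyclic orientation.* An undirected graph isomorphism cannot tell a
patch of tissue from its mirror image, and on nearly homogeneous tissue a
reflected or point-reflected alignment of one region onto another can be
structurally consistent over dozens of cells. Real tissues deform but do
not mirror between frames, so the counter-clockwise cyclic order of a
cell's neighbours — well-defined in the planar embedding — must be
preserved. Every stage that matches cells (seeding, local MCS scoring,
post-processing) requires the cyclic order of a cell's mapped neighbours
to agree with the order of their images.

*Displacement coherence.* A tissue deforms smoothly, so the displacement
vector of a tracked cell should resemble that of at least one tracked
neighbour, even when absolute displacements are large. After cleaning,
a mapping in which more than 20% of cells differ from *all* their
neighbours' displacements by over 1.5 cell lengths is rejected and the
tracker re-seeds. This rejects large spurious alignments (for example a
patch matched onto a structurally similar patch two cell rows away) while
leaving arbitrary rigid translations — which the displacement cutoff
`dMax` alone cannot distinguish — untouched. When the two frames differ
clearly in cell count (cells have entered or left the field of view), a
surviving alignment is additionally required to cover at least half of
the smaller frame before it is accepted outright; otherwise the largest
coherent attempt over all seed retries wins. Mid-extension, the
non-adjacent continuation only accepts cells with a *unique* isomorphic
partner: an ambiguous island started away from the validated seed would
otherwise grow unchecked in homogeneous tissue.

## Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `dMax` | 10 | mean cell lengths | maximal centroid displacement of a candidate pair; deliberately loose (about ten times a typical inter-frame movement) so that positions never drive the matching |
| `minConnections` | 3 | connections | cleaning threshold on preserved tracked-neighbour connections |
| `minClusterSize` | 11 | cells | smallest tracked component kept by cleaning |
| `postMinNeighbours` | 2 | connections | minimum preserved connections to add a pair in post-processing |
| `l` (T1 operator) | 0.2 | cell lengths | length of the new junction edge created by a neighbour exchange |
| `minEdgePx` | 2 | px | polygon edges shorter than this are merged to a midpoint vertex during label-image conversion |

The mean cell length of a mesh is defined as the square root of the mean
cell area — a scale-correct definition that is robust to the cell-size
distribution. The defaults are not tissue-specific; the entire validation
suite runs with them unchanged.

## The synthetic tissue generator

`generateTissue(m, n, g = 8, nLloyd = 4)` emulates epithelial packings:
`(m+g)*(n+g)` Voronoi seeds are dropped uniformly at random in a padded
domain, two rows of evenly spaced guard seeds outside the domain keep all
interior regions bounded (inner row at distance 0.5, spacing 1; outer row
at 1.5, shifted by 0.5), and `nLloyd` steps of Lloyd's relaxation — each
replacing interior seeds by their polygon centroids and re-adding the
guard rows — homogenise the packing. Only polygons whose centroids fall
in the central `m x n` rectangle are kept. The result has roughly `m*n`
cells of mean area 1. At the default four relaxation steps the
polygon-class distribution (about half hexagons, a quarter pentagons, a
fifth heptagons) matches what is reported for columnar epithelia such as
the wing imaginal disc; with more steps the tissue becomes progressively
more lattice-like and *harder* for purely structural tracking, which is
why the validation suite repeats all tests up to fourteen steps.

Guard-row seed counts are one seed per length unit spanning the domain
plus one beyond each corner; the rows' offsets and spacing are the
geometrically meaningful quantities, the exact counts only need to cover
the domain. Lloyd centroids are polygon area centroids, not vertex means,
computed from the Voronoi segment table by fanning triangles around each
(convex) tile.

Perturbation operators build test cases with exact ground truth:
id permutation, window translation (two width-7 windows of a 15x8 tissue
offset by two cell lengths, each re-anchored at x = 0; cell polygons are
clipped at the window planes so that, as in a real imaging window, cells
extending past the field of view remain with their visible part), T1
transition
(edge replaced by a perpendicular edge of length 0.2 through its
midpoint; exactly four cells change neighbour count), T2 removal (cell
collapsed to a vertex shared by its former neighbours, which keep their
mutual rosette edges), and division (random straight cut through the
centroid; crossings within 1e-6 of an existing vertex snap to it, which
is how three- and four-sided daughters arise). `applyRandomT1s()` doses a
tissue with exchanges on a requested fraction of its applicable inner
edges, drawing without replacement and rejecting edges invalidated by
earlier exchanges, so that independent exchanges may touch overlapping
cell sets.

## What the synthetic data do and do not show

The generator reproduces the *packing statistics* and the *event
topology* of epithelia, with exactly known ground truth — that is what
makes quantitative validation possible at all. It does not reproduce
segmentation errors (over-/under-segmentation), imaging noise, curved or
three-dimensional geometry, coordinated morphogenetic flows, or
correlated bursts of divisions. Passing the suite therefore demonstrates
that the algorithm is correct under the stated event types and robust to
tissue homogeneity, not that any particular microscopy dataset will reach
the same success rates. The label-image round trip (rasterise a known
tessellation, re-extract the mesh, compare networks) exercises the
segmented-image pathway end to end, standing in for real segmented
frames.

## Numerical choices and degenerate inputs

- Polygon orientation is normalised counter-clockwise on construction;
  areas and centroids use the shoelace formulas.
- Voronoi vertex identity is exact: adjacent tiles share endpoint
  coordinates bitwise, so mesh topology never depends on a merge
  tolerance. (Vertex keys use 14 significant digits purely as a map key.)
- The branch-and-bound search is budgeted (5e3 node expansions for
  isomorphism tests, 3e3 for candidate scoring). Budgets only bite on
  heavily rearranged neighbourhoods, where scoring is a ranking heuristic
  anyway; all tie-breaks (candidate order, centroid distance, then id)
  are deterministic, so tracking is reproducible bit for bit.
- Repeated seeding is capped (at least 6 attempts, more on small frames);
  if no seed's extension survives cleaning, the largest
  displacement-coherent attempt is kept, which may be empty — the
  tracker then reports everything as untracked rather than guessing.
- Degenerate inputs: meshes need at least three cells and three vertices
  per cell; an edge shared by more than two cells is rejected at
  construction. Label images with fewer than three interior cells raise a
  classed degenerate-frame error. T1 operators require both junctions to
  be three-valent; T2 and division require interior cells; inapplicable
  requests raise classed errors rather than corrupting the mesh.
- Coincident random seeds during generation (probability zero in exact
  arithmetic) are re-drawn.

## Problem sizes in the validation suite

The shipped tests use 9x9 tissues (about 81 cells) for the five canonical
test cases at 100 seeds each, 20x20 tissues (about 400 cells) with ten
replicates per exchange fraction for the rearrangement sweep, ten runs
per relaxation depth for the Lloyd robustness scan, and square tissues of
100 to 900 cells for the scaling fit. These sizes keep the full suite at
roughly a quarter of an hour on one core while leaving every quantitative
comparison at the scale on which the reference numbers are defined.

## Known limitations

- Perfectly regular (hexagonal) tissues admit no unique structural seed;
  the tracker then reports a failure rather than a guess. This is
  inherent to connectivity-only matching.
- Adjacent simultaneous divisions, and divisions whose neighbourhood
  rearranges in the same frame interval, may be unresolvable; they are
  reported as warnings with the involved cells left untracked.
- The division tie-break uses centroid distances and can in principle
  pick the wrong mother when a competing configuration is geometrically
  closer; no such case arises in the validation suite.
- Sequence-level lineage (`trackSequence()`) chains pairwise results;
  an error in one frame pair propagates forward as missing tracks.
- Tissues are assumed planar; 2D projections of strongly curved sheets
  violate the orientation-preservation assumption near folds.
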