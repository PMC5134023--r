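# epimcs — cell tracking in epithelial sheets via maximum common subgraphs

Tracking cells across frames of live-imaging microscopy of epithelial
tissue is what turns segmented movies into biology: rates of cell
rearrangement, division, delamination and growth. It is hard precisely
where it is most interesting — when cells move far between frames (low
temporal resolution forced by phototoxicity), exchange neighbours (T1
transitions), disappear (T2 transitions/death) or divide. Trackers that
match cells by position or shape need small inter-frame changes and
tissue-specific tuning.

`epimcs` matches cells by **connectivity** instead. Each segmented frame
becomes a polygonal tessellation (vertices at junctions where ≥3 cells
meet) and its dual *cell network*: one node per cell, an edge for every
pair of adjacent cells. Two consecutive frames are aligned by a
**maximum common subgraph (MCS)** of their networks — the largest
connected sub-network present in both — built by seed-and-extend:

1. **Seed**: find a pair of cells whose second-order neighbourhood
   networks are isomorphic (centre-anchored, centroids within
   `d_max = 10` mean cell lengths, where mean cell length =
   `sqrt(mean cell area)`).
2. **Extend**: repeatedly add the untracked cell with the fewest
   candidate partners; rank candidates by the size of the *exact* local
   MCS between the two cells' neighbourhood graphs (a branch-and-bound on
   ≤ ~20-node graphs — the trick that makes an NP-hard problem practical
   on planar cell networks). A cell whose complete first-order
   neighbourhood cannot be accounted for is excluded for now.
3. **Clean**: drop pairs with fewer than 3 preserved tracked-neighbour
   connections and tracked clusters of ≤ 10 cells — where connectivity
   carries little information, mismatches concentrate.
4. **Post-process**: greedily add untracked pairs with the most preserved
   connections (≥ 2 required; a cell may not gain more tracked neighbours
   than it preserves), then resolve **divisions** (interior clusters of
   untracked second-frame cells next to cells that gained an edge;
   mother and daughters are their shared neighbours, geometric tie-break
   for 3-/4-sided daughters) and **deaths** (untracked interior cells
   whose neighbours are all tracked).

Planarity is exploited throughout: matches must preserve the
counter-clockwise cyclic order of neighbours (tissues deform, they do not
mirror), and a cleaned mapping must have a locally smooth displacement
field. No parameter is tissue-specific; the whole validation suite runs
with the defaults.

The package also contains the in-silico tissue generator used for
validation — Lloyd-relaxed Voronoi tessellations with guard seeds, plus
perturbation operators (`permuteIds`, `translationPair`, `applyT1`,
`applyT2`, `applyDivision`, `applyRandomT1s`) that produce test cases
with exact ground truth — and conversion between 16-bit label images
(ilastik/watershed-style segmentation exports) and meshes.

## Worked example

Generate a 9×9-cell synthetic tissue, build the canonical
division test case (the central cell is bisected at a random orientation
and all cell ids of the second frame are shuffled), track it, and compare
with the known ground truth:

```r
library(epimcs)

mesh1 <- generateTissue(9, 9, seed = 11)
mesh1
#> CellMesh with 85 cells and 214 vertices
#>   mean cell area 0.962, mean cell length 0.981
#>   bounding box [-0.55, 9.63] x [-0.36, 9.48]

tc  <- makeTestCase("division", seed = 11)
res <- track(tc$mesh1, tc$mesh2)
res
#> TrackingResult: 84 tracked pairs, 1 divisions, 0 deaths
#>   untracked: 0 in frame 1, 0 in frame 2

head(mappingPairs(res), 3)
#>   from to provenance
#> 1    1 29       seed
#> 2    2 64        mcs
#> 3    3 51        mcs

divisions(res)
#>   mother daughter1 daughter2
#> 1     82        80        86

scoreAgainstTruth(res, tc$truth)
#>   fractionCorrect fractionIncorrect fractionUntracked nCells nCorrect nIncorrect
#> 1               1                 0                 0     84       84          0
```

Every one of the 84 trackable cells is paired with its true partner
(`fractionCorrect = 1`), despite the shuffled ids, and the division is
resolved to the correct (mother, daughter, daughter) triple. The
`provenance` column records which stage produced each pair (`seed`,
`mcs` extension, or `post`-processing).

For label-image input use `meshFromLabelImage(readLabelImage("f1.tif"))`;
for sequences, `trackSequence()` chains pairwise results into persistent
track ids with division lineage. Meshes interchange as small JSON frame
files (`writeCellMesh()`/`readCellMesh()`): a `vertices` array with
`id`, `x`, `y` and a `cells` array with `id` and the ordered
counter-clockwise `vertices` id list; tracking results read and write as
tab-separated tables with columns `frame`, `cell_id`, `track_id`,
`event` (`writeTracking()`/`readTracking()`). `vignettes/epimcs-methods.Rmd` documents
the model, the parameters and the design decisions in detail. A thin
command-line wrapper with `generate` / `track` / `evaluate` / `stats`
subcommands is installed at `inst/scripts/epimcs-cli.R`.

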