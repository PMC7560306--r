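---
title: "Skeleton-graph shoot morphometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skeleton-graph shoot morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shootgraph)
```

## The measurement problem

Seedling screening assays produce plate scans: dissected shoots or
coleoptiles laid flat on agar over a blue background, photographed at a
known resolution with a physical scale bar. The traits of interest are
one-dimensional arc lengths — total shoot, internode, individual leaves,
coleoptile — and the task is to extract them automatically for every plant
on the plate, calibrated to millimetres.

`shootgraph` treats each segmented plant as a *skeleton graph*: the binary
silhouette is thinned to a one-pixel-wide medial representation, whose
pixels are classified by their number of 8-neighbours (one → terminal
node, exactly two → edge point, more than two → branching node). Maximal
runs of edge points become edges carrying their pixel polylines; a trait
is then a geodesic path length in this graph.

## Pipeline stages and their parameters

### Preprocessing

* **Median blur** (`medianKernelPx`, default 3 px). Removes scanner salt
  noise. 3 is the smallest kernel that eliminates isolated bright pixels;
  larger kernels also erode organs only a few pixels wide, which shortens
  skeleton ends. The 3×3 case is computed with a vectorized
  median-of-nine sorting network.
* **Bilateral filter** (`bilateralD` = 5 px window, `bilateralSigmaColor`
  = 30 intensity units, `bilateralSigmaSpace` = 3 px). Edge-preserving
  smoothing guided by luminance: range weights are looked up from the
  rounded luminance difference and applied to all three channels. It
  flattens plate texture without blurring organ boundaries.

### Segmentation

Seedlings are segmented by an inclusive HSV window (`hsvBounds`, default
hue 70–180°, saturation ≥ 0.2, value ≥ 0.15) — green tissue against a
blue plate separates cleanly in HSV, and plants are arranged so they do
not overlap, so no instance splitting is needed. Hue wrap-around windows
(`hMin > hMax`) are supported. Coleoptiles carry little colour, so
coleoptile mode converts to grayscale and uses Otsu's threshold: the cut
`t` (classes `I < t` vs `I ≥ t`, scanned over all 256 candidates, ties to
the smallest `t`) that maximizes between-class variance. Which side of
the threshold is "plant" is decided by comparing class means with the
image-border mean — the border is assumed background — which works for
pale tissue on dark plates and dark bars on pale corners alike.

### Partitioning and the minimum-area filter

Foreground components are labelled with 8-connectivity (thin diagonal
organs must stay connected), and components with area ≥
`minDetectionAreaPx` (default 500 px) are kept — *at least*, so a blob
exactly at the stated minimum is detected. Regions are numbered in
reading order of their bounding-box corners, the same numbers used in
CSV output and overlays. The scale-bar corner window is excised before
labelling, because the bar is detected separately.

### Scale-bar detection

The lower corner (`scaleBarSide`) window spans `cornerWindowFrac`
(default 0.15) of the image height and width. The window is
median-blurred, grayscaled, Otsu-thresholded with border polarity, and
the largest component is taken as the bar; its column extent is the bar
width in pixels, and `mm_per_px = scaleBarLengthMM / widthPx` (20 mm by
default). Two guards reject noise: the component must be at least 10 px
wide and must fill at least half of its bounding box (a printed bar is a
solid rectangle; speckle is not). Bar detection is identical in both
plant modes, since the bar's contrast does not depend on plant colour.
For synthetic scenes the generator reports the corner fraction that
encloses its rendered bar; real scans keep the 0.15 default.

### Thinning

Skeletonization uses the classical two-subiteration thinning run to a
fixpoint, which makes it idempotent by construction (rerunning deletes
nothing). It is pixel-identical to a naive per-pixel implementation of
the same algorithm (tested), and retracts free stroke ends by roughly
half the stroke width — the main, irreducible bias of skeleton-based
length measurement. Junctions may thin to small clusters of branching
pixels rather than single pixels; clusters collapse to one node at the
member pixel nearest the cluster centroid, and edge polylines are routed
through that representative so path lengths are conserved across the
cluster. Nodes left with degree 2 (a thinning artifact) are dissolved,
merging their incident edges.

### Edge lengths and the digital metric

Edge length is the geodesic pixel-path length: 1 per orthogonal and √2
per diagonal step. This metric is exact for axis-aligned and 45° paths
but overestimates the Euclidean length of oblique straight segments by up
to 8.2% (at 22.5°) — an intrinsic property of 8-connected digital paths,
not of this implementation. All ground truth in the synthetic generator
is therefore stated in the same digital metric (the chamfer arc length of
the rasterized centerline), which is the quantity a skeleton geodesic
estimates; Euclidean arc lengths are recorded alongside for reference.

### Pruning

Thinning artifacts — plate grid marks crossing a stem, the blunt cut-off
end of the shoot — appear as short terminal spurs. A single pass over the
edges that are terminal in the input graph removes every spur strictly
shorter than `pruneThresholdPx` (default 50 px), with one exception: the
basal edge, i.e. the terminal edge whose endpoint is the bottom-most node
(greatest row; ties to the smallest column), anchors the shoot base and
is never pruned regardless of length. Junctions that drop to degree 2
dissolve afterwards, so a spur at a degree-3 junction removes two nodes
and a spur at a degree-≥4 junction removes one. Pruning is deliberately
*not* iterated to a fixpoint: one pass removes the artifacts the
threshold is aimed at, while iteration could progressively consume real
structure. Coleoptile graphs are never pruned — a whole coleoptile can be
shorter than the threshold.

### Trait extraction

All geodesics are computed from the lowest node with Dijkstra's algorithm
(via igraph; tested against brute-force path enumeration).

* **Total shoot** — geodesic from the lowest to the highest node
  (smallest row, ties to the smallest column). For plants laid upright,
  image-top is plant-top.
* **Internode** — the basal segment of the main path up to its first
  branching node. The graph offers no anatomical landmark below the first
  leaf attachment, so this is a stated convention; branchless plants
  report internode = total shoot with zero leaves and a warning rather
  than failing.
* **Leaves** — every off-path subtree hanging from a junction on the main
  path is one leaf, measured as the farthest geodesic from its junction
  into the subtree; the terminal segment of the main path above the last
  junction is also a leaf. Numbering runs junction by junction from the
  base; where two leaves share a junction the longer one gets the lower
  number (older leaves are longer at this developmental stage).
* **Coleoptile** — the farthest geodesic from the lowest node, full stop.

Lengths convert to millimetres by `lengthPx × scaleBarLengthMM /
barWidthPx`. Summaries report the mean, sample standard deviation (n−1
denominator) and `se = sd/√n` per parameter, per image, and per group
when plants are labelled. `compareMeasurements()` reproduces the standard
program-versus-manual validation protocol: Shapiro–Wilk normality per
list, an F test on the variance ratio, then a pooled-variance two-sided
Student t test.

## The synthetic scene generator

Scanner data cannot ship with a package, so the generator renders what
the imaging protocol prescribes: green plants over a blue background
(`sceneSpec()`), a dark 20-mm bar in a lower corner, optional plate grid
ticks, and seeded salt noise. Plants are built from constant-speed curves
with linearly varying heading: a near-vertical internode (280–330 px at
the default ~10 px/mm), short culm segments between leaf junctions, one
hanging leaf per junction on alternating sides (150–195 px, 46–66° from
vertical — "open leaves", as the protocol demands), and a terminal blade
continuing the axis (210–250 px, the longest leaf, so the shoot top is
its tip). A single-leaf plant is branchless by construction. Strokes are
stamped without anti-aliasing at width 3 px, so the foreground truth is
exact; noise is added only after truth capture, and every draw is fixed
by the scene seed (same spec + seed ⇒ bit-identical files).

Ground truth per organ is the chamfer arc length of the rasterized
centerline. For leaves the truth is measured from the *medial split
point*: two strokes of width `w` render as one fused region until their
centerlines separate by more than `w`, so the medial axis — the object a
skeleton estimates — provably branches only there. The split point is
computed analytically from the spec geometry with sub-pixel
interpolation. Internode and shoot truths are plain centerline arc
lengths, since through-paths pass the junction unaffected.

What the generator does *not* emulate: anti-aliased or blurred organ
boundaries, width variation along organs (real stems taper), overlapping
or closed leaves, shadows, plate reflections, and white-balance drift.
Passing the recovery tests therefore demonstrates the correctness of the
geometry pipeline on clean renderings at the stated noise level, not
robustness to poorly arranged plants — the imaging protocol itself
requires straight, non-overlapping plants with open leaves for accurate
measurement.

## Numerical choices and degenerate inputs

* Thresholds at boundaries: HSV bounds inclusive; minimum area keeps
  `area ≥ min`; pruning removes `length < threshold` (strictly), so a
  50.0-px spur survives.
* Ties: bottom-most/top-most nodes by smallest column; Otsu ties by
  smallest threshold; leaf ties at a junction longest-first.
* Degenerate inputs: constant images are a `degenerate histogram` error
  in Otsu; sub-2-pixel skeletons a `too-small-object` error; a prune that
  would leave fewer than 2 nodes an `all-pruned` error; a missing or
  non-solid bar a `bar-not-found` error. In batch runs these are recorded
  per image in the manifest and the run continues.
* Salt noise and invariance: noise below the median-removal scale cannot
  change the mask interior or background, but a grain landing exactly on
  the plant outline can shift that outline by one pixel (a handful of
  pixels per scene). Tests assert invariance everywhere except the
  outline.
* Problem sizes: recovery tests render one plant per ~800×650 scene and
  check 50 seeded scenes (40 seedling, 10 coleoptile); oracle tests use
  100 images for Otsu and 200 random graphs (≤ 10 nodes) for Dijkstra —
  sizes at which exhaustive oracles are exact and runs stay fast.

## Known limitations

* Skeleton end retraction (~half the stroke width per free end) biases
  every length slightly short; at scanning resolution this is a fraction
  of a millimetre, comparable to the program-versus-manual differences
  reported for tools of this class.
* Leaves that cross or touch violate the tree assumption; cycles are not
  handled and such plants should be re-arranged or post-processed by
  region editing (`mergeRegions()`, drop directives).
* The internode/leaf decomposition is a graph convention; it matches the
  anatomical internode only insofar as the first junction is the first
  leaf attachment.
* Roots are out of scope: the assay measures them manually.
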