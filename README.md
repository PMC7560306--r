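# shootgraph

Automated shoot morphometry for rice (and other cereal) seedlings from
flatbed plate scans. Dissected seedlings are laid flat, non-overlapping and
with open leaves, on an agar plate over a blue background and scanned in
colour together with a 2-cm scale bar in a lower corner. `shootgraph` turns
such a scan into calibrated per-plant measurements — total shoot length,
internode length, ordered leaf lengths, or coleoptile length — plus
per-image and per-group summary statistics, without any manual tracing.

It is aimed at phenotype-based screening: dozens of seedlings per plate,
many plates per treatment, where manual ImageJ measurement is the
bottleneck.

## Method

For each scan the pipeline runs:

1. **Preprocessing** — median blur (salt-noise removal) and bilateral
   filtering (edge-preserving smoothing), then conversion to HSV.
2. **Segmentation** — inclusive HSV colour thresholding separates green
   tissue from the blue plate; for pale, unbranched coleoptiles the image
   is instead converted to grayscale and thresholded by Otsu's method,
   choosing the threshold `t` that maximizes the between-class variance
   `σ²_B(t) = ω₀ω₁(μ₀ − μ₁)²`.
3. **Partitioning** — maximal 8-connected components with area ≥ 500 px
   (noise filter) become plant regions; the lower-corner window is handled
   separately to detect the scale bar, whose pixel width defines the
   mm-per-pixel factor.
4. **Skeleton graph** — each region is thinned to a one-pixel-wide
   skeleton (two-subiteration morphological thinning). Skeleton pixels
   with one, exactly two, or more than two 8-neighbours are terminal
   nodes, edge points, and branching nodes respectively; maximal runs of
   edge points become graph edges with geodesic length (1 per orthogonal,
   √2 per diagonal step).
5. **Pruning** — terminal edges shorter than 50 px (plate grid marks, the
   cut-off end) are removed in a single pass, except the basal edge below
   the lowest node; junctions left with degree 2 dissolve. Coleoptiles are
   never pruned.
6. **Traits** — shortest paths from the lowest node (Dijkstra). Total
   shoot = geodesic from the lowest to the highest node; internode = the
   basal segment of that path up to the first junction; every subtree
   hanging off the path is a leaf (its length the farthest geodesic from
   its junction), as is the terminal segment above the last junction.
   Leaves are numbered from the base, longest first at a shared junction.
   Pixel lengths convert to mm through the scale bar.

A deterministic scene generator (`randomSeedlingScene()`,
`randomColeoptileScene()`) renders synthetic plate scans with exact
per-organ ground truth, so the whole pipeline is testable end to end
without scanner data.

## Worked example

```r
library(shootgraph)

out <- randomSeedlingScene(nPlants = 1, leaves = 2, scene = sceneSpec(seed = 7))
cfg <- analysisConfig(plantType = "seedling",
                      cornerWindowFrac = out$cornerWindowFrac)
res <- analyzeImage(out$image, cfg)

res$bar
#> ScaleBar: 200 px = 20 mm (0.10000 mm/px), left corner

rec <- res$records[[1]]
round(c(shoot = rec$totalShootMM, internode = rec$internodeMM,
        leaf1 = rec$leafMM[1], leaf2 = rec$leafMM[2]), 2)
#>     shoot internode     leaf1     leaf2
#>     54.03     29.12     24.91     16.17

out$truth@plants[[1]][c("shootMM", "internodeMM", "leafMM")]
#> $shootMM
#> [1] 54.14558
#> $internodeMM
#> [1] 29.0799
#> $leafMM
#> [1] 24.55123 15.94756
```

The detected bar (200 px for 20 mm) calibrates all lengths; the measured
shoot, internode and both leaves agree with the generator's analytic
ground truth to a few tenths of a millimetre — the quantization scale of
a skeleton on this raster.

Batch use, CSV export, overlays and grouping go through `runAnalyze()`;
shell scripts wrapping it live in `inst/cli/` (`analyze.R`,
`simulate.R`).

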