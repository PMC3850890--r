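# memseg

Whole-cell segmentation of surface-stained cells in 2D/3D fluorescence
microscopy, with quantitative evaluation of segmentation agreement.

## The problem

Cytoplasmic stains merge densely packed cells into clusters because nothing
marks the boundary between neighbours. A *surface stain* (e.g. a
fluorescent lectin bound to the plasma membrane) draws every cell outline —
including the membranes shared between adjacent cells — as a bright ridge.
`memseg` turns such images into a label volume assigning every voxel to an
individual cell or to background:

1. **Preprocessing** — optional top-hat illumination correction; smoothing by
   coherence-enhancing diffusion (`ced`), edge-enhancing diffusion (`eed`),
   a directional morphological filter (`dirced`, default) or a Gaussian;
   optional subtraction of a Gaussian-smoothed nucleus channel to remove
   spectral bleed-through.
2. **Hessian ridge enhancement** — membranes have strongly negative principal
   curvature; the response `R = max(0, -λ₁)` of the Gaussian-scale Hessian is
   blended with the image to raise membrane contrast.
3. **Markers** — one seed per cell plus one background seed, found
   automatically by adaptive thresholding, derived from a stained-nucleus
   channel (segmented by Otsu-initialized iterative or adaptive thresholding
   with distance-transform splitting of fused nuclei), or painted manually.
4. **Marker-controlled watershed** — floods the ridge landscape so that every
   marker grows exactly one region; boundaries settle on membrane crests.
5. **Classification** — each watershed region becomes cell or background by
   feature thresholds (volume, interior/boundary intensity relative to
   background, convexity) or by overlap with cell markers.

Agreement between two segmentations *A*, *B* is quantified per matched
region pair by

    c1 = |A∩B| / |A∪B|
    c2 = |A∩B| / (|A\B| + |A∪B|),   c3 = |A∩B| / (|B\A| + |A∪B|)

with regions matched one-to-one by the assignment maximizing total c1
(Hungarian algorithm). Aggregates are normalized by the larger cell count,
and automated-vs-observer coefficients can be normalized by the
inter-observer disagreement: `C_i,n = min(1, C_i + (1 − C_i(O1−O2)))`.
Fused / split / false-positive / false-negative cells are counted by a
majority-overlap rule.

A synthetic phantom generator (`generate_phantom()`) builds confluent
surface-stained cell layers with a nucleus channel, vesicle clutter, uneven
illumination, noise, and exact ground-truth labels, so the whole pipeline is
testable without any external data.

## Worked example

```r
library(memseg)

ph <- generate_phantom(phantom_spec(seed = 7))   # 9 cells, 96 x 96 x 8, h = (0.5, 0.5, 1.5) um
res <- segment_surface(ph$stack$channels$surface, minv = 300, maxv = 8000,
                       prm = list(segmsurf = list(
                         getminima = list(method = "nucleus"),
                         classifycells = list(method = "minimacell"))),
                       imnucl = ph$stack$channels$nucleus, h = ph$stack$h)
res
#> surface segmentation: 10 region(s), 9 flagged as cells

cells <- res$labels
cells[!(cells %in% as.integer(names(res$cell_flags))[res$cell_flags])] <- 0L
evaluate_segmentation(cells, ph$truth)
#> segmentation agreement: 9 matched pair(s)
#>   C1 = 0.8747  C2 = 0.8253  C3 = 0.8251
#>   fused 0, split 0, FP 0, FN 0
```

The ten watershed regions are the nine phantom cells plus the background;
all nine cells are recovered, each matching its ground-truth cell with a
Jaccard-family c1 near 0.87 (the residual disagreement is the one-voxel
ambiguity of the membrane crest), and no cells are fused, split, missed or
invented.

A command-line interface is installed as `exec/memseg`, with subcommands
`batch`, `segmsurf`, `segmct`, `evaluate`, `phantom` and `overlay`; batch
jobs process folders of `stackN.tif` files driven by a YAML parameter file
(`run_batch()` from R).

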