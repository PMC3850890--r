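---
title: "Whole-cell segmentation of surface-stained cells: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-cell segmentation of surface-stained cells: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memseg)
```

## The segmentation model

A surface stain marks the plasma membrane, so every cell outline — including
the membrane shared by two adjacent cells — appears as a bright, roughly
one-to-two-voxel-wide ridge. `memseg` models segmentation as flooding of a
ridge landscape: each cell supplies one *marker* (seed), one marker
represents the background, and a marker-controlled watershed assigns every
voxel to the basin of exactly one marker, placing boundaries on the ridge
crests. The assumptions are:

* membranes are locally the brightest structures and (after smoothing)
  topologically closed around each cell;
* every cell contains exactly one marker strictly inside its membrane —
  marker *position* within the cell is otherwise irrelevant;
* cell volumes lie within user-supplied physical bounds `minv < maxv`
  (µm³), from which the expected cell diameter
  `d = (6·maxv/π)^(1/3)` is derived wherever a length scale is needed.

The pipeline in `segment_surface()` runs, in order: nucleus-channel
subtraction (when a nucleus image is supplied), top-hat illumination
correction (when enabled), smoothing, Hessian ridge enhancement, marker
detection, watershed, feature computation and classification. When both
channel subtraction and illumination correction are active, subtraction
runs first: bleed-through is a channel property and should be removed
before background-field estimation.

## Smoothing operators

Four operators stand behind `smooth_image()`; all default to planewise
operation (membranes are acquired plane by plane, and the planewise result
equals applying the 2D operator to every plane independently — an exact
identity kept under test).

* **`dirced`** (default): an orientation bank of grayscale
  closing-then-opening with a line element (default length 9 voxels, 8
  orientations), taking per voxel the maximum response over orientations.
  Closing along the locally best direction bridges staining gaps in
  membranes up to roughly half the line length; the subsequent opening
  removes isolated bright specks (vesicles). Output is bounded by the input
  range by construction.
* **`ced`** — coherence-enhancing diffusion: the diffusion tensor shares the
  structure tensor's eigenvectors (scales `sigma = 1`, `rho = 3` voxels)
  with eigenvalues `α` across and `α + (1−α)·exp(−C/(µ₁−µ₂)²)` along the
  coherent direction; constants `α = 0.001`, `C = 1` are the standard 2D
  choices. Explicit scheme, default time step 0.15 in 2D and 1/12 in 3D —
  within the stability bounds 1/4 and 1/6 of the explicit discretization,
  enforced with an error. The 3D path decomposes the 3×3 structure tensor
  numerically per voxel and is intended for small volumes; planewise is the
  practical default.
* **`eed`** — edge-enhancing diffusion for blob-like objects (nuclei,
  cytoplasmic stain): diffusivity across the regularized gradient is
  suppressed with a Perona–Malik function `1/(1 + |∇u|²/λ²)` (default
  `λ = 0.05` on a unit-range image) inside the tensor frame, driving the
  image towards piecewise constancy while keeping edges sharp.
* **`gaussian`**: a truncated separable kernel (default radius 4, sd 1
  voxel) for gentle general-purpose smoothing; strong Gaussian smoothing
  erodes exactly the membrane detail the watershed needs.

Boundaries are handled by symmetric (edge-inclusive) reflection everywhere:
this preserves constants, conserves total intensity under normalized
kernels, and avoids dark rims. Smoothing scales are expressed in voxels and
applied isotropically in-plane; physical-unit anisotropy enters only where
distances matter (splitting, volumes).

## Ridge enhancement

Bright ridges have strongly negative principal curvature, so the smallest
eigenvalue λ₁ of the Gaussian-scale Hessian (scale 2 voxels by default) is
strongly negative on membrane crests. The response `R = max(0, −λ₁)` is
invariant under adding a constant and, after normalization, under positive
scaling of the image. The output blends normalized image and normalized
response, `(1−w)·n(im) + w·n(R)` with `w = 0.5`. This is deliberately the
simplest curvature measure satisfying the required contrast behaviour; it
also responds to bright blobs (for a rotationally symmetric blob
λ₁ = λ₂ < 0), which is why images with heavy vesicle clutter are better
served by nucleus markers with ridge filtering disabled. Multi-scale
vesselness filters are out of scope; the measure is an extension point.

## Markers

* **Automated** (`minima_automated()`): at a reference plane (mid-plane by
  default; the plane of maximal total intensity with `level = "strong"`,
  appropriate for tissue where that plane is the most complete), a voxel is
  "membrane" when it exceeds its local mean over a window of diameter
  `d·(1+a)` (`a = 0.02`) by more than `a` times the intensity range. The
  membrane-free connected components of the plane, eroded by one voxel,
  become cell markers when their extruded volume lies in `[minv/4, maxv]` —
  a marker need only sit inside its cell, hence the lowered floor.
  Components touching the image border cannot be membrane-enclosed and are
  dropped. The largest border-touching membrane-free component becomes the
  background marker (this definition is package plumbing; any below-ridge
  sea connected to the frame would do). Markers are stamped into a single
  plane; the watershed floods the rest of the stack from there.
* **Nucleus** (`minima_from_nuclei()`): the nucleus channel is segmented by
  `segment_nuclei()` (volume floor `minv/10` — nuclei occupy roughly a
  tenth of the cell volume) and each nucleus, eroded by one voxel, becomes
  one cell marker. Fused nuclei are split (below) so adjacent cells keep
  separate markers.
* **Manual**: user-painted masks. `minima` alone defines all markers;
  `minimacell` alone is completed with an automatic background marker;
  given both, `minimacell ⊆ minima` is enforced. Manual markers take
  priority over the nucleus route when both are configured.

## Nucleus segmentation and splitting

`segment_nuclei()` binarizes by either **iterative thresholding** (default):
start at `th × Otsu` and lower the threshold by a factor 0.95 per step until
the largest foreground component reaches the minimum volume — using the
largest component (not total foreground) guarantees at least one valid
candidate; or **adaptive thresholding**: foreground where the voxel exceeds
its local mean by `adth` times the intensity range, with a window radius of
cell order (slow in 3D, hence planewise).

Fused objects pinch at the fusion waist. `split_cells()` computes, at one
reference plane, the Euclidean distance transform of the foreground in
physical units (anisotropic voxel spacing respected; exact two-pass
lower-envelope transform), finds its extended maxima at depth `splitth`
(default 1 µm; smaller values split more aggressively), and runs the
marker-controlled watershed on the negated distance map, cutting where the
distance to one maximum equals the distance to another. The default
reference plane is one third of the stack height — cultured cells rest on
the substrate, so that plane passes through the nucleus bodies. The 2D cut
is propagated by stamping the plane labels down each foreground column;
3D components that never reach the reference plane keep one fresh label
each, and slivers created by the stamping inherit their column's label, so
the output labels partition the input foreground exactly (a tested
invariant).

## Watershed

`watershed_markers()` is an immersion watershed: the landscape is quantized
to 256 levels and flooded level by level, within a level in breadth-first
waves so basins grow geodesically. Connectivity is 8 in 2D and 26 in 3D.
Where two basins claim a voxel in the same wave — the watershed line — the
voxel goes to the region whose marker centroid is nearest, ties to the
lower label: the output is a full partition with no line voxels, exactly
one region per marker component (tested over hundreds of random marker
configurations).

## Volume limits, features, classification

Users state whole-cell volume limits; a stack covering less than one cell
diameter in z observes smaller volumes. With `s = min(1, nz·hz/d)`,
`adjust_volume_limits()` uses `minvol = s·minv` and
`maxvol = maxv·(s + (1−s)/2)` — full stacks unchanged, partial stacks
strictly reduced, the maximum less aggressively so that oversized
border-merged candidates are still rejected. This realization is one
admissible choice satisfying the stated inequalities.

Per-region features: physical volume; mean interior and mean
boundary-shell intensity, both normalized by the background mean (the mean
intensity over background-marker regions, or `meanintbck` when the image
has almost no background, as in tissue); and two convexity measures. With
no qhull binding available, convex hulls are computed planewise on the
voxel point set and aggregated: region area over hull area, and hull
perimeter over region boundary length, both ≤ 1 up to voxelization.

Classification (`classify_cells()`) is a conjunction of the active gates —
`volume` within limits, `intincell ≤ 10` (interiors several-fold brighter
than empty background are tolerated; solidly bright debris is not),
`intborder ≥ 2` (a membrane must surround a cell), `convexarea ≥ 0.4`,
`convexperim ≥ 0.4`. These defaults are the package's own: the features are
normalized by *background* intensity, so useful interior thresholds sit
well above 1. With cell markers available, `method = "minimacell"` accepts
regions overlapping a cell marker subject to the volume gates — the volume
gates stay active because a cell merged into the background would otherwise
be accepted. Classification is monotone: relaxing any single threshold
never shrinks the accepted set.

## Evaluation

Pairwise coefficients `c1 = |A∩B|/|A∪B|` (more conservative than Dice),
`c2 = |A∩B|/(|A\B|+|A∪B|)`, `c3 = |A∩B|/(|B\A|+|A∪B|)`; c2 and c3 are
bounded by c1 and `c2(A,B) = c3(B,A)`. High c3 with low c2 flags
under-segmentation of B relative to A. Regions map one-to-one; the
assignment maximizes total c1 via a shortest-augmenting-path Hungarian
solver (no LSAP solver is available as a dependency), tested against
exhaustive enumeration. Aggregates divide the summed pairwise coefficients
by `N = max(n_cells_A, n_cells_B)` — per-pair averaging, with unmatched
cells contributing zero, penalizes missed and spurious cells symmetrically
(pooling voxels globally is the other reading of the normalization; the
per-pair form is the package's choice and is stated wherever reported).
Inter-observer normalization `C_i,n = min(1, C_i + (1 − C_i(O1−O2)))` adds
the disagreement between two expert observers so only disagreement beyond
human variability is penalized; the cap at 1 makes the observer pair's
self-comparison exactly 1. Error counts use a majority rule (> 50% of the
smaller region): reference cells sharing their majority automated region
are falsely fused; a reference cell majority-covered by k ≥ 2 automated
regions contributes k−1 falsely split events; automated regions with no
majority partner are false positives, reference cells with none are false
negatives. The majority rule is the package's own; only the counts
themselves are standard.

## The phantom generator

`generate_phantom()` emulates a confluent layer of surface-stained cultured
cells: seeded territories (dart-thrown centres with a minimum spacing,
nearest-centre partition in physical units, radius-clipped) form the sheet;
the membrane is a bright shell *centred on* the territory boundary — a
surface stain marks the outline itself, and observers trace the membrane
middle; nuclei are one ellipsoidal blob per cell at 45% of the cell radius,
with a configurable fraction of pairs pulled into surface contact across a
shared boundary; vesicle speckles, a linear illumination ramp (15%), and
Gaussian noise (sd 0.03 against a unit membrane peak) complete the image.
Cell centres sit at one third of the stack height (cells rest on the
substrate); the sheet is morphologically closed by the membrane width, so
no sub-membrane background corridors or enclosed lagoons remain — neither
occurs in a truly confluent layer. Defaults: 96×96×8 voxels at
(0.5, 0.5, 1.5) µm, 9 cells of 6–9 µm radius.

What the phantom does *not* model: optical point-spread blurring beyond a
small Gaussian, photobleaching, intensity saturation, binuclear cells, and
tissue-like absence of background. Passing the phantom suite therefore
demonstrates the pipeline's mechanics (marker generation, flooding,
splitting, classification, bookkeeping) under controlled conditions, not
performance on any particular microscope's data.

## Numerical choices and degenerate inputs

Quantization of the watershed landscape to 256 levels; ties inside a
flooding wave broken by marker-centroid distance, then lower label.
Constant images: smoothing operators are exact identities; nucleus
segmentation returns zero regions; Otsu raises a degenerate-histogram
error. Empty marker sets abort the surface pipeline with a diagnostic
rather than returning an empty labeling. The extended-maxima depth
comparison uses half the smallest positive level difference as the plateau
tolerance. Batch processing treats every per-stack error as a logged skip;
determinism: all generator randomness flows through one seed, and re-running
a batch reproduces label volumes bit-exactly.

## Problem sizes used in the test-suite

The suite exercises 2D phantoms of 64–128² pixels and 3D phantoms of
96×96×8 voxels with 4–10 cells — small enough for interactive runs while
large enough that every cell carries tens of membrane, nucleus and interior
voxels per plane. The same generator scales to arbitrary sizes for users'
own experiments.

## Known limitations

The ridge measure does not discriminate ridges from bright blobs (see
above). Marker extraction is single-plane; cells absent from the reference
plane are not seeded. The iterative threshold's 0.95 lowering factor is a
fixed geometric step, not a line search. The planewise convexity features
differ from true 3D hull measures for strongly tilted cells. The 3D
coherence-diffusion path is O(voxels) eigen-decompositions in R and is
practical only for small volumes.
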