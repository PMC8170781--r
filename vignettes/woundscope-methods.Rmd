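---
title: "Quantifying wound-healing assays at cell and population scale"
author: "WoundScope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying wound-healing assays at cell and population scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(WoundScope)
```

## The problem

In a scratch (gap-closure) assay, two confluent cell monolayers separated by
a cell-free gap of roughly 500 µm close the gap by migration and
proliferation, observed by time-lapse microscopy (typically one frame every
15 minutes). Two levels of description matter:

* **cell scale** — positions, density and velocity of individual cells;
* **population scale** — the monolayer as an entity: position and
  protrusion length of its gap-facing *leading edge*, and the closure time.

Conventional analyses threshold grey values (adaptive local-mean threshold,
Canny edges) and degrade under noise, uneven illumination and debris.
WoundScope implements both the conventional routes and a learned route: a
small U-net that segments individual cells (background / cell / cell-border),
from which both scales are derived, plus a direct monolayer/gap variant.

## The synthetic scene generator

No public live-cell reference data accompany this problem, so the package
ships a generator whose output carries complete ground truth: every
downstream stage is testable against known cell positions, masks, velocities
and edges. A scene consists of:

* two monolayers of textured ellipses (Gaussian radial intensity profile
  with multiplicative speckle that translates rigidly with the cell),
  placed by inhibition sampling so neighbouring cells keep a visible
  intercellular border; radii are drawn from a truncated normal
  (default mean 12 µm, sd 2 µm);
* a vertical gap (default 500 µm) centred in the image;
* kinematics: cells within a configurable band (`borderBandUm`, default
  36 µm = three mean radii) of the gap front move toward
  the gap centre at `vEdgeMmH` (default 0.03 mm/h, the scale of measured
  endothelial front speeds), the left/"upstream" edge scaled by
  `1 + asymmetry` and the right by `1 - asymmetry`, emulating the faster
  upstream edge seen under flow; widening the band to the monolayer width
  yields coherent sheet migration, which sustained closure requires — a
  narrow directed band outruns the static interior and tears off after a
  few frames. Interior cells take per-frame isotropic
  Gaussian steps with no inertia (kinematic prediction brings no benefit
  for cell motion that is not continuous over time); the component standard
  deviation is calibrated so the *mean* step speed equals `vInnerMmH`;
* optional cell division (daughters placed 1.5 radii away; counts are then
  non-decreasing), per-frame fractional jitter of the ellipse axes
  (`deformation`, default 0.1) standing in for cell shape change, a linear
  illumination ramp, and additive Gaussian noise (`addGaussianNoise`,
  default variance 0.01 — the classic default of the usual noise filter)
  applied separately so clean/noisy pairs share ground truth.

Ground truth per frame: cell records (continuous centroid, pixel area,
instantaneous velocity in mm/h), a cell-id label map, a 2-class
monolayer/gap mask (union of cell masks closed with a disk of twice the mean cell radius —
the closing must bridge the inhibition-placement spacing of 2.4 radii, or
the "closed sheet" keeps false pockets whose frayed boundary would
contaminate the true edge), and the true edge positions x(y).

What the generator deliberately does **not** emulate: phase-contrast
optics, shear-flow hydrodynamics, cell-cell adhesion and collective-motion
correlations, lineage structure. Tests passing on these scenes therefore
demonstrate the correctness of the measurement pipeline, not performance on
real microscopy; the printed validation numbers of any specific instrument
or cell line are not reproducible from synthetic data.

A note on the physical calibration: the package default is 1.4 µm/px at
15 min frame interval, chosen so that the customary tracking radii of 25
and 30 px correspond to maximum linkable speeds of 0.14 and ~0.17 mm/h,
the values usually quoted for endothelial monolayers
(`maxLinkableSpeed(25)`).

## Segmentation

**Adaptive local-mean threshold** (`adaptiveThreshold`). The local mean is
an exact box average over a window (default 161 × 121 px, large enough to
straddle cells and background) with mirror-reflected borders, computed via
an integral image; reflection avoids darkened borders biasing the
threshold. A pixel is foreground iff `value > mean * 2 * (1 - s)`. The
literature describes the sensitivity `s` only behaviourally — more pixels
pass as it grows, 0.5–0.7 being useful — so the rule is the simplest factor
that reduces to "above the local mean" at `s = 0.5` and is monotone in `s`.
Dark-cell polarity applies the same rule to the inverted image. Note that
for `s > 0.5` the factor drops below 1, so uniform non-zero regions (the
empty gap included) pass the threshold — on clean images sensitivities at
or just above 0.5 segment best, while the 0.6–0.7 range trades that for
aggressiveness on faint cells; this is also why the adaptive route degrades
first when noise arrives. Holes are
filled and components below `minCellAreaPx2` (default 50 px², below any
plausible cell) removed. Detections are 8-connected components (diagonal
protrusions stay attached) with centroid and area; ids are assigned in
raster order of each component's first pixel, so results are reproducible.

**U-net** (`trainUNet` / `predictUNet`). Three encoder stages of two 3 × 3
ReLU convolutions and 2 × 2 max pooling, a dropout-regularized bridge
(rate 0.5), and a mirrored decoder of 2 × 2 stride-2 transposed
convolutions with skip concatenation; feature widths double per stage from
`baseFeatures`; a 1 × 1 convolution and softmax give per-pixel class
probabilities. Training minimizes the Tversky loss
`1 - (TP + s)/(TP + alpha FP + beta FN + s)` averaged over classes
(class-mean by default; `tverskyConfig(classes =)` restricts the average to
a subset, e.g. the cell class alone), with soft confusion counts, defaults alpha 0.3 / beta 0.7
(false negatives weighted more), Adam at learning rate 0.001 multiplied by
0.9 per epoch, mini-batches (default 30, though small desk-scale runs
converge faster with smaller batches and correspondingly more updates),
shuffling before each epoch, and optional on-the-fly augmentation (up to
100 per image: rotation ±180°, skew ±10°, translation ±10 %, brightness
±20 % — kinds from standard practice, ranges ours; geometric transforms hit
image and label identically, labels by nearest neighbour). Images are
min-max normalized to [0, 1] per image.

Numerical choices worth recording:

* **Transposed-convolution init.** The four sub-pixel blocks of each 2 × 2
  transposed convolution are initialized identically (an
  upsampling-equivalent start, in the spirit of bilinear deconvolution
  initialization). With independent He init the early network exhibits a
  2-px checkerboard parity that desk-scale training budgets do not reliably
  erase; starting parity-free removes the artifact without constraining the
  trained solution.
* **Arbitrary frame sizes.** Every pooled dimension must be even, so frames
  are mirror-padded to the next multiple of `2^nStages` and cropped back;
  mirroring also avoids border artifacts on cells touching the frame edge.
  Grid-aligned extra padding leaves interior predictions unchanged (a
  property the tests check).
* **Determinism.** All randomness (init, shuffling, dropout, augmentation)
  draws from R's RNG under the seed in `trainConfig`; single-threaded runs
  reproduce loss histories exactly.

Per-cell output post-processing (`postprocessICD`) follows the learned
route's standard recipe: 3 × 3 median filter on the label map (kernel size
our choice), border class set to background so touching cells separate,
cell class binarized, sub-minimum components dropped — this last step is
what makes the route robust to debris with implausible cell size.

The direct monolayer/gap variant (`predictIDSD`) is the same architecture
with 2 classes trained on monolayer masks.

## Cell-scale metrics

* **Density** (`densityProfile`): the image is split into 50 half-open
  columns (last closed); a cell belongs to the column containing its
  centroid. The default unit is cells/mm² (count over column area); a
  per-width variant (cells/mm) is exposed because both normalizations are
  in circulation.
* **Tracking** (`linkFrames` / `trackSequence`): globally greedy
  nearest-neighbour linking — candidate pairs within the motion radius `R`
  sorted by distance (ties by ids) and accepted one-to-one. Greedy global
  matching, rather than independent per-cell nearest neighbours, prevents
  two cells claiming one target; conflict resolution is otherwise
  unspecified in the field's descriptions. Tracks terminate at their first
  miss — no gap closing, since linking is strictly frame-to-frame. `R`
  should exceed the largest per-frame displacement; 25–30 px at the default
  calibration bounds linkable speeds at 0.14–0.17 mm/h, above typical cell
  speeds (< 0.1 mm/h).
* **Velocity profile** (`velocityProfile`): per-step speed
  `distance × pixel size / Δt`, assigned to the column of the step's start,
  averaged as magnitudes (not vectors) per column; empty columns are
  flagged undefined rather than zero.
* **CIV** (`civField`): two-pass normalized cross-correlation velocimetry,
  windows from 64 × 64 down to 32 × 32 px at 50 % overlap, FFT correlation,
  3-point Gaussian sub-pixel peak fit, peak-ratio validation (threshold
  1.5, second peak sought outside a 5 × 5 exclusion around the first).
  The commercial adaptive-correlation implementations are proprietary; only
  window sizes and overlap follow common settings. CIV measures the
  coherent grey-value shift of a window, not individual cells — on scenes
  with uncorrelated cell motion, deformation and division it systematically
  underestimates the tracking speed (the tests assert the direction, about
  a factor of two on default scenes, not an exact factor).

## Population-scale metrics

`edgeFromCells` upscales per-cell masks to a monolayer: dilate with a disk
of radius 15 px (the customary "radial dilation by 15"; the element shape
is not specified in the field's descriptions, a disk is the natural
reading) so neighbouring cells merge; keep the two largest 8-connected
components — this single rule removes debris, which is never among the two
monolayers; erode each back by the same radius. The gap is the largest
background component touching both monolayers, and each leading edge is the
ordered run of monolayer boundary pixels 4-adjacent to the gap, traced on
the Moore boundary. This definition excludes image-border pixels and is, we
find, the only formalization consistent with the usual pictures of
"the edge".

Edge metrics: protrusion length = 8-connected chain length (1/√2 steps)
plus one pixel, so a straight edge spanning k rows measures exactly
k · pixel size (each pixel contributes its full extent; without the +1 a
k-pixel chain has only k−1 steps); spatially averaged position = mean x of
the polyline. `edgeTimeSeries` collates both per frame and side, derives
the gap width (right mean minus left mean) and the closure time (first
frame whose detection signals a closed gap; frame 1 is time 0).
`edgeFromCanny` is the conventional route (Canny → dilate by 1–20 px →
remove small components → erode → same tracing); whether its erosion radius
equals the dilation radius is exposed as a parameter. Canny edges fray —
on phantoms its edge length is never below the true length, and debris near
the edge strictly increases it, while the cell route is unchanged; the
tests assert these directions.

## Evaluation metrics

IoU per class with empty∪empty defined as 1 (avoids spurious zeros on
background-only tiles); boundary F1 with a distance-transform matcher and a
default tolerance of 0.75 % of the image diagonal (the customary
convention; no tolerance is canonical); count comparison via the paired
two-sided t-test (a p-value without a named test accompanies published
count comparisons; the paired t on per-frame counts is the natural choice),
with explicit flags when fewer than two frames or constant differences make
the p-value undefined; elementwise relative errors with zero-reference
flagging.

## Problem sizes and tests

The test-suite and the acceptance script run entirely on generated scenes
at desk scale, chosen as the smallest sizes at which each property is
cleanly measurable: segmentation scenes of 320 × 240–512 × 384 px with
~60–260 cells; velocity recovery on a 512 × 512 px, 20-frame scene
(~5000 tracking steps, so every defined column mean carries hundreds of
samples); U-net training on 200 patches of 128 × 128 px for 6 epochs with
mini-batches of 2 (600 Adam updates — enough, with the parity-free init,
to reach held-out cell IoU above 0.9 on clean scenes). Training patches
include noise-distorted copies (variances 0.005 and 0.01) so the learned
segmentation, like its real counterpart trained on imperfect images, stays
robust under the noise level used in the distortion experiments.

## Known limitations

* The renderer's cells are bright textured ellipses; contrast inversions,
  halos and phase artifacts of real microscopy are absent, so trained
  weights do not transfer to real images — retrain on labelled frames of
  the target instrument (the workflow `samplePatches` → `trainUNet` is the
  same).
* The tracker has no division handling: a daughter cell starts a new track,
  and a division next to the parent can momentarily distort the local speed
  estimate.
* Edge reconstruction assumes one vertical gap between two monolayers;
  multiple wounds or closed islands would need a different gap-selection
  rule.
* The CIV validation is a plain peak-ratio test; advanced outlier
  replacement (median tests, vector interpolation) is out of scope.
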