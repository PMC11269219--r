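---
title: "Measuring radicle length from segmentation masks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring radicle length from segmentation masks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radiclemetry)
```

## The measurement problem

The elongation of the embryonic root (radicle) during seed germination is a
standard indicator of seed vigour. High-throughput phenotyping rigs image a
tray of germinating seeds (typically a 6 × 6 grid on a 25 cm × 25 cm frame,
cropped to 1500 × 1500 px) at fixed intervals, and an instance-segmentation
model supplies one binary mask per detected radicle. This package takes over
from that point: it turns per-seed masks into calibrated physical lengths and
per-seed growth curves.

The chain is:

1. **Mask merging** — per-instance masks are cast to 8-bit, resized to the
   original image size (nearest neighbour, so masks stay binary), summed, and
   thresholded to `{0, 255}`. The result is the union of all instance
   foregrounds, conventionally written to `in.png`.
2. **Edge detection** — a from-scratch Canny chain: Gaussian smoothing,
   Sobel gradients, non-maximum suppression (NMS), and double-threshold
   hysteresis.
3. **Contour measurement** — edge pixels are partitioned into 8-connected
   contours; each pixel counts exactly 1 regardless of diagonal adjacency.
4. **Calibration** — the half-perimeter rule converts a contour's pixel
   count `n` to a length:
   `length_cm = n / 2 × R`, with `R = actual_length_cm / image_side_px`.
   For the standard setup `R = 25 / 1500 = 1/60` cm/px. The rationale: the
   closed edge contour of a thin elongated object is roughly twice the
   object's length, so half of it approximates the length itself.

No thickness correction is applied; a radicle of thickness `t` contributes
its two rounded end caps to the contour, giving a positive bias of roughly
`t/2 × R` for axis-aligned shapes. Tests quantify rather than correct it.

## The synthetic generator as ground truth

Real imagery has no exact per-radicle arc length, so every stage is tested
against a generator with known truth. A radicle is a Catmull–Rom spline
through ordered control points, rendered by sweeping a disc of diameter
`thickness_px` along the curve; the ground truth is the spline's arc length,
computed by adaptive polyline refinement to a 1e-3 px tolerance. Continuous
coordinates place integer values at pixel corners, so an axis-aligned
unit-thickness centerline of arc length L rasterises to exactly L pixels —
this makes the trivial cases exactly checkable.

Random radicles come from a bounded-curvature random walk: a heading drawn
uniformly on the circle, changed by at most 25° per ~10–30 px step, reflected
at the cell walls. These defaults emulate the meandering and bending of real
radicles on a horizontal tray; they were fixed at design time and are not
adjusted per experiment. Growth series truncate one fixed centerline at
scheduled arc lengths, with a slow/plateau/fast default schedule (8, 1 and
30 px per hourly interval) mirroring the germination pattern seen in hourly
time-lapse data, where the growth rate peaks late.

What the generator does **not** emulate: seed-coat texture, illumination
gradients, segmentation noise, touching or intertwined radicles from
neighbouring seeds, and shoot structures. Passing tests therefore validate
the *computation* on clean masks; they do not bound errors introduced by an
upstream segmentation model on real photographs.

## Numerical choices in the edge chain

* Gaussian kernel: sampled, normalised to sum 1; default σ = 1.4 on a 5 × 5
  support. Borders use symmetric (edge-including) reflection everywhere, so
  constant images are fixed points and no artificial border gradients
  appear.
* Gradients: 3 × 3 Sobel, Euclidean magnitude, `atan2(Gy, Gx)` direction
  with the row axis pointing down.
* NMS: directions quantised to four bins (0°, 45°, 90°, 135°); a pixel
  survives iff its magnitude is `≥` both neighbours along the binned
  direction, with out-of-image neighbours counting as zero. Ties are kept
  (`≥`, not `>`) so symmetric profiles do not vanish entirely.
* Hysteresis: strong ≥ high, weak in `[low, high)`, weak kept when
  8-connected (transitively) to a strong pixel. Defaults (50, 150) on the
  8-bit magnitude scale. The connectivity is computed sparsely (foreground
  pixels as graph vertices); tests check it against an iterative-dilation
  oracle.
* Defaults are conventional Canny practice; the source imagery never pins
  them down, so all are configuration.

## A known, quantified limitation: orientation-dependent edge counts

Pixel-count length estimation is not isotropic, and the effect is large
enough to deserve its own section. Quantised NMS emits one surviving pixel
per scan line crossing the edge. For an edge at angle φ from the nearest
axis, the scan-line crossing density per unit edge length is `cos φ` when
the gradient falls in an axis bin (|φ| < 22.5°) but `cos φ + sin φ` — up to
√2 — in the diagonal bin. Diagonal edges therefore carry up to ~41% more
pixels per unit length than axis-aligned ones, and the half-perimeter rule
inherits that overestimate. This is not an artefact of this implementation:
on a synthetic 45° bar, a widely used reference edge detector produces the
byte-identical doubled staircase, and the package's chain is tested
pixel-for-pixel against an independently written reference on random images.

Consequences, measured on this package's own synthetic ensembles
(thickness 3 px, lengths 30–300 px, isotropic initial heading, bounded
curvature):

* near-axis radicles recover their length to within a few percent with a
  small positive thickness bias;
* isotropically oriented curved radicles are overestimated by ~15–20% on
  average, with individual errors from −9% to +41% depending on how much of
  the centerline runs diagonally.

`scripts/acceptance.R` recomputes and reports these recovery errors at run
time rather than hiding them. Users comparing machine lengths against manual
measurements should expect the machine series to run high for diagonal
growth; the agreement regression (`agreement_analysis()`) makes the
systematic component visible as a slope above 1. A skeleton/medial-axis
length estimator would be isotropic, but the half-perimeter pixel-count rule
is the method this package implements, so the limitation is documented, not
silently corrected.

## Tracking and the amplified-average transform

Seeds sit at fixed tray positions, so tracking is association by grid cell:
the image is partitioned into equal cells, each contour is assigned to the
cell containing its centroid, and the largest contour wins a contested cell
(the rest are logged). This avoids identity switches that nearest-neighbour
tracking can produce when radicles cross cell borders marginally. Missing
detections — common in early germination, when short radicles resemble
background noise — are recorded as missing, never interpolated; growth rates
simply span the longer interval.

Interval growth rates are first differences of calibrated lengths over time.
For display, the amplified-average transform `(mean length − offset) ×
scale` with defaults offset 1 cm and scale 2 magnifies trends in the mean
curve; it is a visualization aid, both constants are parameters, and nothing
downstream consumes the transformed values.

Contour overlays rescale pixel coordinates by `R` into axis units of 0.1 cm
and arrange frames side by side in time order, with each contour's cm length
anchored beneath its bounding box.

## MSCA attention numerics

The package also provides the pure forward pass of a multi-scale
convolutional attention (MSCA) block, the building block of the attention
encoder used by modern segmentation backbones: a 5 × 5 depthwise aggregation
of the input `F`, three depthwise strip-convolution branches (1 × k then
k × 1, k ∈ {7, 11, 21}) approximating large dense kernels, a skip branch
contributing the aggregated map itself, a 1 × 1 channel mix forming the
attention map `Att`, and elementwise gating `Out = Att ⊙ F`. No nonlinearity
is applied between the branch sum and the mix, and none after gating. Since
`Att` is linear in `F`, the output is homogeneous of degree 2 — a property
the tests exploit. The encoder's downsampling block (3 × 3 stride-2
convolution, padding 1, then per-channel batch normalization) is included,
with reflection padding chosen for consistency with the rest of the block.
Training, initialisation and any decoder are out of scope; weights are
user-supplied or generated deterministically from a seed for testing.

## Evaluation arithmetic

Average precision uses greedy matching in descending confidence (each ground
truth consumable once, IoU at or above the threshold) and integrates the
precision–recall curve with all-points interpolation: the precision envelope
is made monotone non-increasing and integrated over recall steps, which
matches the continuous integral definition exactly for finite data. Users
comparing against 101-point COCO-style values should expect small
differences on sparse data. `map_range()` evaluates the 10 thresholds
0.50–0.95 in steps of 0.05 and averages them; boxes are continuous and
half-open with no +1 area convention. Convolution complexity follows the
closed forms `flops = 2·H·W·(C_in·K² + 1)·C_out` and
`params = C_in·K²·C_out` in exact integer arithmetic.

## Problem sizes used in tests

The shipped test-suite and acceptance script run entirely on generated
data: random 32 × 32 images for the edge-chain reference comparison,
420 × 420 single-radicle images for length recovery (40–50 radicles),
300 × 300 2 × 2 trays for the pipeline round trips, and one 1500 × 1500
mask for the PNG round trip. These sizes were chosen to exercise every code
path, including full-resolution I/O, while keeping a complete run in the
tens of seconds on one CPU.

## Worked example

```{r example, eval = FALSE}
library(radiclemetry)

cal <- calibration_ratio(25, 1500)        # 1/60 cm per pixel

sp <- random_radicle_spec(c(1, 1), 1, 1, image_size = c(420, 420),
                          length_px = 180, thickness_px = 3, rng_seed = 7)
g  <- generate_radicle_mask(sp)

merged <- merge_masks(instance_mask_set(list(g$mask), c(420, 420)))
edges  <- canny(merged$grid)
measure_contours(edges, cal)
g$true_length_px * cal$R                  # generator ground truth, in cm
```
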