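---
title: "Methods: detector design, enhancement metrics, and the synthetic pen model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detector design, enhancement metrics, and the synthetic pen model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caprimon)
```

`caprimon` implements a monitoring pipeline for housed cashmere goats built
around a four-state ethogram: lying, standing, drinking, eating. This
vignette explains the models and procedures in the package, the parameters
that matter, the design choices made where the design was genuinely open,
and what the synthetic fixtures do and do not demonstrate about real data.

## The detector family

The core model is a compact one-stage anchor-free detector. Its reference
layout is the familiar n-scale plan: channel widths 64/128/256/512/1024
scaled by a width multiple of 0.25 (so 16/32/64/128/256), C2f repeats
3/6/6/3 scaled by a depth multiple of 0.33 (so 1/2/2/1), an SPPF block
(kernel 5) closing the backbone, a top-down plus bottom-up feature-pyramid
neck with four C2f fusion blocks, and a decoupled head at strides 8/16/32.
The head's box branch uses hidden width `max(16, P3/4, 4·reg_max) = 64` and
predicts a `4 × reg_max` distribution over distance bins (`reg_max = 16`);
the class branch uses hidden width `max(P3, nc) = 64`. Boxes are decoded as
the expected bin value times the stride around each anchor point. With four
classes this plan has 3,011,612 trainable parameters, counting convolution
and dense weights, biases, and batch-norm scale/shift (running statistics
are buffers, not parameters).

Three lightweight variants rebuild the C2f bottlenecks while keeping the
C2f dataflow (split, n bottlenecks with all intermediate outputs
concatenated, fuse):

- **GC bottleneck** (`gnca`, and the `gsca` backbone): ghost module →
  channel attention → ghost module, with a residual connection when the
  stage is marked shortcut. The ghost module uses the classic defaults:
  ratio 2 (half the output channels come from a dense 1×1 "intrinsic"
  convolution, half from a cheap depthwise 3×3 on those), batch norm and
  SiLU on both halves.
- **SC bottleneck** (`snca`, and the `gsca` neck): GSConv → channel
  attention → GSConv. Following the usual slim-neck bottleneck convention,
  the first GSConv uses a 1×1 dense half and the second a 3×3 dense half;
  both use a depthwise 3×3 companion and a perfect-interleave channel
  shuffle.
- The channel-attention unit inside both bottlenecks is a
  squeeze-excitation-style gate: global average pool, bottleneck MLP with
  reduction 16, sigmoid.

The named variants insert CBAM after each of the four neck fusions (channel
gate from shared-MLP average and max pooled descriptors, then a 7×7 spatial
gate) and train with the Alpha-CIoU box loss. `fpn_attention` can instead
select squeeze-excitation, coordinate attention, or embedded-Gaussian
non-local attention behind the same interface. Two of these deserve a note:

- *Coordinate attention vs. channel attention.* The acronym "CA" is used
  for both in the lightweight-detection literature. Inside the bottlenecks
  we implement the squeeze-excitation reading (a pure channel gate), which
  is the simpler and more common construction there; `attention_block("ca")`
  provides a directional (per-row/per-column pooled) coordinate-attention
  gate for the FPN, with the shared bottleneck convolution applied to each
  pooled descriptor separately rather than to their concatenation — a
  simplification that keeps the implementation small without changing the
  gating structure.
- *Non-local attention* initializes the batch norm of its output projection
  at zero, so a freshly built block is exactly the identity; this is the
  standard stabilization for residual attention.

Resulting sizes at `nc = 4`: baseline 3.01 M, `gnca` 2.15 M, `snca` 2.36 M,
`gsca` 2.25 M. The strict ordering `gnca < gsca < snca < baseline` is
structural: ghost bottlenecks cost about `1.1·c²` parameters per hidden
width `c` against `18·c²` for the standard pair of 3×3 convolutions, and SC
bottlenecks about `5.1·c²`. These counts follow from the stated
constructions; published figures for models of this family vary by a few
percent across reports depending on unstated block details, so the package
treats its own layer-by-layer bookkeeping (tested against an independent
analytic recomputation) as the ground truth for what *this* construction
costs.

## Training objective and the smoke trainer

The loss is `7.5·L_box + 1.5·L_dfl + 0.5·L_cls` (weights exposed via
`loss_weights()`). `L_box` is selectable among CIoU, EIoU, SIoU and
Alpha-CIoU (default power `a = 3`, the published default for the
alpha-weighted family); the CIoU trade-off `α = v/((1 − IoU) + v)` is
treated as a constant during differentiation, the standard practice.
`L_dfl` is the distribution focal loss: cross-entropy of the per-side bin
distribution against the two integer bins bracketing the continuous target,
weighted by proximity. `L_cls` is mean binary cross-entropy with logits.

Assignment uses a *static center-prior top-k rule*: candidate anchors are
those whose point falls inside a ground-truth box, each truth keeps its ten
closest candidates, and conflicted anchors go to the nearest truth.
Positives receive one-hot class targets. A task-aligned (prediction-aware)
assigner is the modern default for full-scale training, but its alignment
scores are near-degenerate in the first few hundred steps from random
initialization; the static rule gives stable targets and a clean,
reproducible optimization signal at smoke-fit scale, which is the regime
this package trains in. The classification bias of the head is initialized
to logit(0.01) so that a fresh detector predicts rare positives.

`fit_smoke()` runs Adam (lr 0.001, weight decay 1e-5 applied to
convolution/dense weights only) with mixup augmentation on half of the
batches (`λ ~ U(0.4, 0.6)`). The network, including reverse-mode automatic
differentiation, is implemented in R on channels-last matrices; every
operation's gradient is verified against numeric differentiation in the
test suite. Default smoke-fit problem sizes — ten 160×160 scenes
letterboxed to a 64×64 input, batch 4, 200 steps — are chosen so a fit
completes in about a minute on one CPU core while still demonstrating that
the full assignment/loss/backprop path optimizes (loss falls roughly
sixfold and training-set mAP rises from 0 to above 0.9). This demonstrates
correctness of the machinery, not deployment-grade accuracy: reaching
field-level mAP requires real footage and GPU-scale training, which is out
of scope.

## Night enhancement and its metrics

CLAHE partitions the image into a 16×16 tile grid, clips each tile's
256-bin histogram at `clip_limit` times the uniform bin height
(`clip_limit = 4` by default), redistributes the excess uniformly
(iterating the residual a few times), maps levels through the scaled
cumulative distribution, and blends the four surrounding tile mappings
bilinearly at every pixel. Color images are processed on the luminance
channel with chrominance rescaled by the luminance ratio — the common
practice that avoids hue shifts; a per-channel mode exists behind
`channels = "rgb"` because the luminance convention, while standard, is not
the only defensible one. A constant image stays spatially constant under
CLAHE, though its level can drift by a few gray values through the clip
redistribution — an inherent property of clipped equalization, documented
rather than hidden.

Two metrics quantify enhancement. *Discrete entropy* is the Shannon entropy
of the gray-level histogram in bits (0 for a constant image, 8 for a
uniform 256-level histogram); it measures information content and is
position-invariant by construction. The *edge-based contrast measure*
follows the gradient-weighted construction: for each interior pixel,
`e` is the mean of its 8-neighborhood weighted by 3×3 Sobel gradient
magnitude (plain mean where all neighbor gradients vanish), the local
contrast is `|x − e|/(x + e)` (0 where the denominator is 0), and the
image score is the mean over interior pixels — a ratio form invariant to
uniform intensity scaling. The acronym's source formula is not reproduced
in most applied reports; this package states its construction exactly so
the metric is reproducible.

`paired_enhancement_study()` runs before/after metrics over an image set
(at least 10 images) and tests the one-sided hypothesis that each metric
increases with a paired Wilcoxon signed-rank test — chosen over a paired
t-test because metric deltas over heterogeneous scenes have no reason to be
normal. All-zero difference sets return p = 1 directly, since the signed
ranks are undefined there.

## Augmentation semantics

`vertical_stitch()` is intentionally rigid: it only accepts equal widths
and never resamples, crops or drops a box — the point of the operator is
exact label conservation while moving the composite's aspect ratio toward
the square detector input (for 1280×720 sources, letterbox padding falls
from 0.4375 to 0.111 of the canvas). A symmetric `horizontal_stitch()` is
provided with the same contract. `mosaic()` scales four images by seeded
factors, anchors them at a seeded center split, clips boxes to their
quadrant, and drops a box when its clipped area falls below
`min_box_area_frac` (default 0.25) of its scaled pre-clip area — the rule
that reproduces mosaic's label-loss behavior on tightly packed herds. The
drop rule is defined against the *scaled* area so that scaling alone never
triggers it; only genuine cutting does. `mixup()` blends pixels and takes
the exact union of the label sets.

## The monitoring layer

The online pipeline samples one representative frame per elapsed second
(the first frame in that second; whether real systems average within the
second is unstated in field descriptions, and no smoothing is applied by
default), detects, counts boxes per class, and appends one record row per
second with the fixed schema `Date,Time,Standing,Drinking,LyingDown,
Feeding`. Time budgets are `Σ count × period` goat-seconds per behavior;
`compare_budgets()` reports per-behavior relative differences plus the
pooled feeding+standing difference, the reconciliation check for the
systematic trough ambiguity (an animal with its head in the trough may be
"feeding" to the detector and "standing" to an observer). The three
operation modes map to variants as fast → `snca`, balanced → `gnca`,
precise → `gsca`.

`evaluate_map()` matches detections to truths greedily at IoU ≥ 0.5 in
descending confidence, each truth used at most once, and integrates the
precision–recall curve at 101 recall points; classes absent from the
ground truth are excluded from the mean with a warning rather than scored
0, so a fixture without drinking goats does not silently deflate mAP.

## The synthetic pen model

The generator emulates the geometry and bookkeeping of top-down pen
footage, not its appearance. A scene is a textured floor with a feed-trough
strip along the top edge and a water point in the bottom-right corner;
each goat is a flat-shaded ellipse cluster whose pose encodes its class:
lying animals are low-aspect blobs, standing animals elongated blobs with a
drop shadow, eating animals overlap the trough, drinking animals the water
point. Stocking density maps 2 m²/goat (high) and 3 m²/goat (low) to pixel
area at a fixed 60 px/m scale; placement rejects candidates whose body-box
IoU with an already placed animal exceeds `occlusion_level`, and raises an
error after bounded retries — deliberately, so impossible configurations
fail loudly instead of degrading silently. Night lighting applies a gamma
compression (2.2) plus Gaussian sensor noise (σ = 4), which measurably
lowers entropy and edge contrast, giving the enhancement study a
directionally realistic substrate.

Ground-truth boxes default to the full drawn extent of each animal
(amodal), matching how annotators box partially hidden animals; a
`box_mode = "visible"` flag shrinks boxes to the pixels that remain visible
after occlusion, since annotation practice varies and neither convention is
universal. Determinism is strict: every public generator routine seeds a
private RNG stream and restores the caller's state, so a seed fully
determines pixels, boxes and video records.

What passing tests on these fixtures shows: exact label bookkeeping through
every operator, correct loss/gradient/assignment machinery, correct record
and budget arithmetic, and the direction of the enhancement effect. What
they cannot show: detection accuracy on real goats, robustness to lighting,
camera pose or breed appearance, or the field error rates of the recording
system — those require real footage.

## Numerical choices and degenerate inputs

- Box coordinates are 0-based half-open `[x1, x2) × [y1, y2)` internally;
  VOC files are written with 1-based inclusive integer corners, so a
  read/write round trip is exact for integers and within 0.5 px otherwise.
  Whether a given annotation tool exported 0- or 1-based corners is
  absorbed by that tolerance.
- Zero-area boxes yield IoU 0 with a warning; loss denominators carry an
  epsilon of 1e-9; DFL targets outside `[0, reg_max − 1]` are clamped with
  a warning.
- NMS is class-wise greedy by descending confidence with ties broken by
  lower row index; a detection is suppressed when IoU with a kept box
  strictly exceeds the threshold.
- Frame streams yield `⌊N/interval⌋` frames starting at index 0; timestamps
  are `index / fps`.
- `letterbox()` centers the content with `floor` padding and gray value
  114; its box transform composed with its inverse is the identity within
  one pixel (the pixel is lost to integer canvas rounding, not to the
  transform).
- Batch norm uses batch statistics in training and running statistics
  (momentum 0.1, ε = 1e-5) in evaluation; weight init is He-scaled normal.

## Known limitations

- Inference in pure R is desk-scale: a 64×64 forward pass takes a fraction
  of a second, a 640×640 pass several seconds. The package targets
  correctness, testability and small-scale experimentation, not throughput.
- Parameter counts of the lightweight variants depend on block details
  (ghost ratio, depthwise kernels, attention reduction) that differ across
  published implementations of the same ideas; this package fixes one
  defensible construction and documents it above.
- Video I/O is an image-sequence abstraction (PNG directories, in-memory
  frames); no codec bindings are included, so MP4/AVI sources must be
  exported to frames upstream.
- The generator's behavior-switching model is memoryless per second; it
  produces valid record streams but not realistic bout durations.
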