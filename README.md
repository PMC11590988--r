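# caprimon

Camera-based behavior monitoring for housed cashmere goats.

Continuous welfare monitoring of housed goats means watching pen cameras
around the clock and logging, second by second, how many animals are lying,
standing, drinking, or eating. Doing this by hand is slow and error-prone;
`caprimon` packages the computer-vision pipeline that automates it: a
lightweight one-stage detector family sized for edge hardware, the
image-enhancement and augmentation steps that make night footage and
occluded herds learnable, and the online recording layer that turns
detections into an ethogram time budget. Everything is exercisable on a
seeded synthetic pen-scene generator, so the whole pipeline is testable on a
desk with no camera, GPU, or data download.

It is aimed at researchers in precision livestock farming who want a
transparent, fully scriptable reference implementation of this kind of
monitoring stack — every stage, from the VOC annotation parser to the
backpropagation through the detector, is plain R that can be read, probed,
and unit-tested.

## What is inside

**The detector family.** A compact anchor-free one-stage network: a stem
plus four C2f stages (split–transform–concatenate residual blocks) with an
SPPF pooling head in the backbone, a top-down/bottom-up feature-pyramid
neck, and a decoupled head that predicts, at strides 8/16/32, per-anchor
class logits and a discrete distribution over `reg_max = 16` distance bins
per box side (decoded by its expectation). Three lightweight variants
rebuild the C2f bottlenecks:

| variant    | backbone bottleneck | neck bottleneck | FPN attention | parameters |
|------------|--------------------|-----------------|---------------|------------|
| `baseline` | standard (two 3×3 convs) | standard  | none          | 3.01 M     |
| `gnca`     | ghost → CA → ghost | ghost → CA → ghost | CBAM       | 2.15 M     |
| `snca`     | GSConv → CA → GSConv | GSConv → CA → GSConv | CBAM   | 2.36 M     |
| `gsca`     | ghost → CA → ghost | GSConv → CA → GSConv | CBAM     | 2.25 M     |

A *ghost module* factorizes a convolution into a small dense 1×1 map plus
cheap depthwise 3×3 operations; *GSConv* pairs a half-width dense
convolution with a depthwise companion and a channel shuffle; *CA* is a
squeeze-excitation-style channel gate; *CBAM* adds a 7×7 spatial gate.
`attention_block()` also provides coordinate attention and embedded-Gaussian
non-local attention for comparison.

**Losses.** The training objective is
`L = 7.5·L_box + 1.5·L_dfl + 0.5·L_cls`, with `L_box` selectable among the
IoU penalty family:

- CIoU: `1 − IoU + ρ²/c² + α·v`, where `ρ` is the center distance, `c` the
  enclosing-box diagonal, `v = (4/π²)(arctan(w_t/h_t) − arctan(w/h))²` and
  `α = v/((1 − IoU) + v)`;
- EIoU: width/height gap terms over the enclosing box;
- SIoU: angle-modulated distance cost plus shape cost;
- Alpha-CIoU: `1 − IoU^a + (ρ²/c²)^a + (α·v)^a` (default `a = 3`).

`L_dfl` is the distribution focal loss (weighted cross-entropy against the
two bins bracketing the continuous regression target) and `L_cls` binary
cross-entropy. All are verified against independent oracles (pixel
enumeration for IoU, straight-line scalar re-derivations for the rest).

**Night enhancement.** Contrast-limited adaptive histogram equalization
(clip limit 4, 16×16 tile grid by default, applied to luminance) with two
quantitative metrics — the edge-based contrast measure (mean of
`|x − e|/(x + e)` with `e` the gradient-weighted 8-neighborhood mean) and
the discrete entropy of the gray-level histogram — plus a paired one-sided
Wilcoxon study over an image set.

**Augmentation.** Vertical stitching (two 1280×720 frames become one
1280×1440 composite, conserving every label exactly and nearly halving the
gray letterbox padding: `gray_fill_fraction()` drops from 0.4375 to 0.111),
2×2 mosaic with an explicit box-survival rule, and pixel mixup.

**Monitoring.** Frame streams, keyframe sampling, per-second behavior
records (`Date,Time,Standing,Drinking,LyingDown,Feeding`), ethogram time
budgets, system-vs-manual budget comparison, and a VOC-style mAP evaluator
(greedy matching at IoU ≥ 0.5, 101-point interpolated AP, confidence
threshold 0.001, NMS 0.5).

**Synthetic scenes.** `generate_pen_image()` renders a top-down pen —
textured floor, trough strip, water corner — with goat-like blobs whose pose
encodes the behavior class, at two stocking densities (2 and 3 m²/goat at
60 px/m) and day/night lighting, with exact ground-truth boxes, fully
determined by a seed. `generate_video()` adds per-second behavior switching
and the matching ground-truth record stream.

## Worked example

```r
library(caprimon)

# a seeded synthetic pen scene with ground truth
scene <- generate_pen_image(pen_scene_config(c(640, 480), n_goats = 8, seed = 7))
scene
#> <annotated_image> 640x480 px, 8 box(es), source 'pen-seed7'
#> drink   eat lying stand
#>     1     3     3     1

# the hybrid lightweight detector
det <- build_detector(detector_config("gsca"), seed = 1)
det
#> <goat_detector> variant 'gsca', 4 classes, attention 'cbam'
#>   2,248,499 trainable parameters (2.25 M)

# night-enhancement study on 12 seeded night scenes
night <- lapply(1:12, function(i) generate_pen_image(
  pen_scene_config(c(320, 240), n_goats = 3, lighting = "night",
                   occlusion_level = 0.5, seed = i))$pixels)
st <- paired_enhancement_study(night, clahe_params(4, c(16, 16)))
round(st$p_values, 5)
#>    ebcm      de
#> 0.00126 0.00126
round(st$mean_delta, 3)
#>  ebcm    de
#> 0.078 1.610
```

The enhancement raises the edge contrast by 0.078 and the histogram entropy
by 1.6 bits on average, both one-sided significant at p < 0.01: night scenes
carry measurably more usable detail after CLAHE. A 200-step smoke fit of the
baseline detector on ten trivially separable 160×160 scenes
(`fit_smoke(det, imgs, steps = 200)`, Adam at lr 0.001, weight decay 1e-5,
mixup on) drives the total loss from ≈11.6 to ≈1.9 and the training-set mAP
from 0 to ≈0.94 in about 70 s on one CPU core — the full
assignment/loss/backprop path optimizes.

A thin command-line front end (`inst/cli/caprimon.R`) exposes `simulate`,
`enhance`, `augment`, `build-info`, and `monitor` subcommands over the same
functions.

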