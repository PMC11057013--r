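---
title: "Detecting and grading peanut pod rot: models, losses and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and grading peanut pod rot: models, losses and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(podrot)
```

## The problem

Grading pod rot severity on a single peanut plant means counting how many
of its pods are visibly rotten. Phenotyping for resistance breeding needs
this done over many plants, and the imagery is hostile to counting: pods
adhere to each other and to soil-colored roots and stems, and rotten pods
share their dark coloration with rotten stems and leaves. `podrot` frames
the task as two-class object detection (`G` non-rotted, `R` rotten)
followed by an arithmetic grading step, and packages the whole pipeline —
data handling, detector, training, evaluation, grading, and a synthetic
scene generator that stands in for field imagery during testing.

## Detector architecture

The detector is the standard compact one-stage design: a CSP backbone
(stem convolution, four stride-2 stages each ending in a C3 bottleneck
block, SPPF), a PAN-style feature-fusion neck, and a coupled convolutional
prediction head at strides 8/16/32 with three anchors per scale and
`3 × (5 + 2)` output channels per grid cell. Two width presets exist:

* `small` — the standard small-model scaling (backbone C3 widths
  64/128/256/512, depths 1/2/3/1, input 640);
* `tiny` — all widths divided by 8 and single-bottleneck C3 stages,
  input 320. Every experiment in the test suite and the acceptance script
  uses `tiny`; it trains in minutes on one CPU core and exercises exactly
  the same code paths.

One wording conflict was resolved deliberately: descriptions of this
detector family sometimes call the head "decoupled", but the stock small
variant uses a coupled head, and that is what `podrot` builds.

### Shuffle Attention placement

`insertSAAfterC3()` inserts one Shuffle Attention block directly after each
backbone C3 stage — and only there; neck C3 stages are untouched. Each SA
block splits its `C` channels into `G` groups, halves each group into a
channel-attention sub-feature (gated by
`sigmoid(scale · GAP(x) + shift)`) and a spatial-attention sub-feature
(per-channel instance normalization with `eps = 1e-5`, then an elementwise
sigmoid gate), concatenates, and applies the
reshape–transpose–flatten channel shuffle with `G` groups so information
crosses group boundaries. Three design points the family leaves open were
fixed as:

* **Group count `G`**: not derivable from the architecture description;
  the package defaults to `G = 16` for `small` (keeping `C/(2G) ≥ 2` at
  the narrowest insertion site) and uses `G = 4` for `tiny` (whose
  narrowest C3 width is 16).
* **Split ratio**: the two branch halves are equal (1:1).
* **Weight sharing**: none — each insertion site owns its parameters,
  which matches the reading that attention is applied per layer to spread
  the learning load. Per site that is `4G · C/(2G) = 2C` parameters, an
  identity the tests assert against the built networks.

Affine gate parameters initialize to scale 1, shift 0, so an untrained SA
block passes a half-gated but undistorted signal; the zero-parameter
configuration (gate exactly 0.5) is used in tests because its output,
`0.5 × channelShuffle(x, G)`, is known in closed form.

## Localization losses

`ciouLoss()` implements
`1 − IoU + ρ²(b, b_gt)/c² + αv` with the piecewise weight `α = 0` for
`IoU < 0.5` and `v/(1 − IoU + v)` otherwise; `eiouLoss()` replaces the
aspect term with explicit size differences,
`(w − w_gt)²/c_w² + (h − h_gt)²/c_h²`, interpreting `ρ²` applied to the
scalar widths as the squared difference. EIoU is the training default;
CIoU remains selectable so the ablation can toggle the delta.

Numerical choices: the denominators `c²`, `c_w²`, `c_h²` are guarded with
`1e-9` — except that exactly identical boxes short-circuit to a loss of 0,
since the expression is 0/0 at coincidence. `focalEiouLoss()` provides the
IoU-powered focal weighting (`IoU^γ × EIoU`) discussed in the EIoU
literature for class-imbalanced regression; because it is not clearly part
of the original training recipe it is implemented, tested, and **off by
default**.

## Training

Targets are assigned YOLO-style: for each ground-truth box, every anchor
whose width and height ratios to the box are all below 4 claims the grid
cell containing the box center, at each of the three scales; the first
claimant wins a contested (anchor, cell) slot. The loss is

* objectness: binary cross-entropy over every cell/anchor (target 1 at
  assigned sites), with per-scale balance weights (4, 1, 0.4);
* classification: BCE on the two class logits at assigned sites;
* localization: EIoU (or CIoU) between the decoded box and its target.

Component gains default to (box 0.05, obj 1, cls 0.5); `totalLoss()` then
sums the three parts with unit weights. The decode is the standard
`(2σ(t) − 0.5 + cell)·stride` for centers and `(2σ(t))²·anchor` for sizes.

Gradients flow through an engine written for this package: im2col
convolutions (RcppArmadillo) with hand-derived backward passes for every
layer — fused conv+BN+SiLU (BN `eps 1e-3`, momentum 0.03, backward through
the batch statistics), C3/SPPF composites, SA (including the instance-norm
backward), upsampling, concatenation and the heads. The complete network
gradient is verified against central finite differences in the test suite.
One deliberate exception: the derivative of the localization loss with
respect to the four decoded box coordinates is computed by central finite
differences (step `1e-3` relative) and chained analytically through the
decode. The box loss is a scalar function of four well-scaled inputs, the
assigned sites number a few dozen per batch, and this matches the
convention of treating `α` as a constant during differentiation; the cost
is negligible and the gradient is exact to rounding.

Optimization is Adam (β₁ 0.9, β₂ 0.999, eps 1e-8) with global gradient-norm
clipping at 10. The full-scale configuration mirrors the published training
setup — 200 epochs, batch 32, initial learning rate 0.01, two classes —
but is not a desk-scale computation; the smoke preset used throughout the
tests is `tiny`, 320 px, batch 4, lr 0.003, ≤ 20 epochs. With 72 training
scenes and 12 epochs this reaches a held-out synthetic mAP@0.5 in the
60–90% range (seed-dependent) from an untrained baseline of 0%.

## Grading

`rottenPodRate()` is `N_R/(N_G + N_R)`; `podRotGrade()` maps the rate onto
the five-level ordinal scale with knots at 0, 10%, 25% and 50%. The prose
form of such scales is ambiguous exactly at the knots; the package fixes
**left-open/right-closed** intervals uniformly — a rate of exactly 0.10 is
Level 3, 0.25 is Level 5, 0.50 is Level 7 — which keeps "greater than 50%"
exact for Level 9. An image with no detections is undefined under the rate
formula (0/0); it is reported as rate 0, Level 1, with an `empty` flag and
a warning, so batch runs survive. The report writer emits one txt file per
image plus an aggregate table whose columns are: image id, non-rotted
count, rotten count, total, rate, grade. The workflow this mirrors pins
down columns 2, 3, 5 and 6 explicitly; column 4 = total is an inference.
The table is written both as CSV and as XLSX; since no spreadsheet writer
is available to depend on, the package writes the OOXML container itself
(a stored zip with CRC-32 computed in R), which the suite validates with an
independent zip reader.

## Evaluation

Matching is greedy per class at IoU ≥ 0.5 (the family default; the
threshold is an argument): predictions in descending confidence claim the
highest-IoU unmatched truth. AP uses 101-point recall interpolation by
default (all-point integration is selectable) over predictions pooled
across images; mAP is the mean over the two class APs × 100. The
image-level criterion behind comparison precision (CP = 100·AS/RS) is
operationalized **strictly**: an image counts toward AS only with zero
false positives and zero false negatives in both classes, the strictest
reading consistent with error narratives in which both missed pods and
duplicated boxes disqualify an image. CP is rounded half-up to two
decimals to match the precision such tables print. A five-fold
cross-validation harness (`kfoldSplits()`) provides seeded, maximally
equal partitions.

## Dataset pipeline

VOC XML corners are converted to continuous center format; YOLO txt files
are normalized center format with class index 0 = G, 1 = R and six
decimals. The seven augmentation primitives — noise, cutout, rotation,
cropping, translation, horizontal flip, vertical flip — apply in that
fixed canonical order; `randomAugment()` samples a seeded 5-subset,
mirroring a pipeline that randomly combines five of them. Magnitudes are
nowhere specified at the source, so they are configuration defaults chosen
to keep labels valid: Gaussian noise σ ∈ [5, 15] on the 8-bit scale, up to
3 cutout squares of ≤ 10% image width, rotation within ±15°, crop scale
≥ 0.7 per axis (resized back to the original canvas), translation up to
20%. Boxes retaining under 25% of their area after cropping/cutout/
clipping are dropped — a conventional retention rule, also configurable.
The 9:1 train/test split uses `round(n × 0.9)` training items after a
seeded shuffle. Rotation is implemented by inverse nearest-neighbor
mapping in the package itself so that the box-corner transform provably
matches the pixel transform (a consistency the tests check on a rectangle
fixture); image resizing goes through EBImage.

## Synthetic scenes

`generateScene()` draws elliptical pods — tan with light speckle for `G`,
dark brown with black mottling for `R` — over a noisy soil background with
curvilinear distractor strokes that deliberately share the rotten palette,
because distinguishing rotten pods from rotten stems and roots is the
documented confound of this imagery. Exactly `round(nPods × rottenFraction)`
pods are rotten. The three adhesion strata constrain pairwise ground-truth
box IoUs by construction: `none` — all zero; `slight` — at least one pair
in (0, 0.3] and none above; `severe` — at least one pair above 0.3. The
0.3 boundary is artifact-defined (the field strata are visual) and
configurable. Boxes are the tight axis-aligned bounds of each rotated
ellipse. `generateValidationSet()` reproduces the stratified validation
design (n per stratum × 3 strata; 50 × 3 at full scale, scaled down in
tests).

What passing tests on these scenes shows — and does not. The generator
reproduces the *structure* of the task: two visually distinct classes, box
overlap from adhesion, distractors with confusable color statistics, exact
labels. It does not model field lighting, perspective, pod texture
variability, soil occlusion, or annotation noise. Synthetic results
therefore validate the pipeline's correctness and the relative behavior of
its components, not field accuracy; headline field-scale numbers require
the original imagery and GPU-scale training and are explicitly out of desk
scope.

## Problem sizes and reproducibility

The suite and acceptance script use: 80 scenes (320², 8 pods, rotten
fraction 0.3, strata cycled) with a 72/8 split and 12 epochs for the smoke
learning check; 45 scenes with 8 epochs inside the acceptance script; a
12-scene, 3-epoch, 160² preset for the 2×2 ablation; 500 random instances
for the AP oracle; 1,000 random pairs for the IoU oracle; all count pairs
with total ≤ 200 for the grade-scale exhaustive check. These sizes are the
package's chosen smoke scale. Every stochastic step (scene content, weight
initialization, shuffles, splits) takes an explicit seed, and scene
generation restores the caller's RNG state.

## Known limitations

* The `small` variant is provided and structurally tested but not trained
  in the suite; only `tiny` is exercised end to end.
* Mosaic augmentation and rotated boxes are out of scope; so are GIoU/DIoU
  variants, SE/CBAM attention baselines, and the rotten-kernel rate.
* The statistical significance test attached to published ablation tables
  is unspecified at the source and is not reproduced.
* Detection quality at smoke scale is bounded by the tiny width preset and
  short schedules; the numbers it produces are demonstrations of learning,
  not accuracy claims.
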