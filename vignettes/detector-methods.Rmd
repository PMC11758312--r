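---
title: "A set-prediction detector for camera-trap imagery: model, losses, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A set-prediction detector for camera-trap imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camtrapdetr)
```

## The problem

Camera traps produce wildlife images under three recurring difficulties:
animals partially hidden by vegetation, motion or defocus blur, and
low-light night captures. `camtrapdetr` implements a DETR-family
(set-prediction) detector aimed at these regimes, built from four
architectural ideas:

1. a **multi-channel coordinate attention** mechanism that pools the deep
   feature map along three directions (height, width, and a global channel
   sum) and refines it with a product of directional gates — positional
   information that helps with occluded animals;
2. a **multi-dimension feature aggregation** path that fuses shallow,
   intermediate and deep pyramid levels through aggregation (Fuse) blocks
   and re-parameterizable convolution (RepC3) blocks — cross-scale context
   that helps with blurred animals;
3. a **lightweight terminal backbone stage**: the last ResNet-18 stage is
   replaced by a GELAN-style RepNCSPELAN4 block (CSP channel split, two
   re-parameterizable sub-branches, concatenation, transition), cutting
   the model size roughly in half at matched accuracy claims;
4. the composite **VariFocal + GIoU + L1** training objective over
   Hungarian-matched query/truth pairs.

Because no deep-learning framework is available to R here, the package
carries its own small tensor layer: feature maps are plain `[C, H, W]`
arrays, convolutions run as im2col matrix products, and a reverse-mode
differentiation tape provides exact gradients for every operator. This
keeps every architectural computation inspectable and testable, at the
price of speed — the package trains *toy* models on CPU; it does not
attempt GPU-scale training.

## Model structure

The backbone taps three scales: `s4` at stride 8, `s5` at stride 16 and
`s7` at stride 32 (stages 2, 3 and the terminal stage of the ResNet-18
layout). The deep map is projected to the model width and processed by
two parallel branches — the coordinate attention module and one standard
self-attention encoder layer with 2-D sinusoidal positions (AIFI) — whose
outputs are summed before entering the aggregation path (a config switch
composes them serially instead; the published figure shows both feeding
the aggregation module without fixing the composition).

### Coordinate attention

For input $x \in \mathbb{R}^{C\times H\times W}$ the module computes a
width-averaged column $Z^{(h)} \in \mathbb{R}^{C\times H\times 1}$, a
height-averaged row $Z^{(w)} \in \mathbb{R}^{C\times 1\times W}$, and the
*unnormalized* global sum $Z^{(ch)} \in \mathbb{R}^{C\times 1\times 1}$
(the sum, not the mean, is deliberate and tested). The concatenated
H/W encodings pass through a 3×1 convolution + frozen batch norm + SiLU
(`F1`, with reduced width $C' = \max(8, C/32)$, the usual
coordinate-attention reduction), are restored to $C$ channels by a 1×1
convolution, and gated by a sigmoid (`F2`). A per-channel gate `F3` is the
spatial average of batch-normalized `F2` times a 1×1 convolution of
$Z^{(ch)}$. The attention tensor is the broadcast product of the five
directional factors
$F1_h \cdot F1_w \cdot F2_h \cdot F2_w \cdot F3$.

Two points were genuinely open and are resolved as package design
choices, each behind a flag:

* The printed attention product does not mention the input $x$; taken
  literally the module would discard its input entirely. The default
  multiplies the attention product onto $x$, as channel-attention modules
  conventionally do; `literal_eq5 = TRUE` restores the bare product.
* "Upsampling" of `F1` has no spatial target (its spatial extent is
  already $H{+}W$); it is interpreted as channel restoration
  $C' \to C$ via a 1×1 convolution, and the `F1` factors pass through the
  same restoring map so that all five factors broadcast over
  $[C, H, W]$. The `F1` factors stay unbounded (only the `F2` factors are
  sigmoid "attentional weights"); the batch normalization attached to the
  channel branch sits after the sigmoid, inside that branch only.

### Aggregation path

Each Fuse block takes a shallow map (2× spatial), a middle map and a deep
map (½× spatial): `f1 = Down(Bconv1(f_up))`, `f2 = Bconv1(f_middle)`,
`f3 = Upsample(f_down)`, output `Bconv1(concat(f1 + f2, f1, f3))`. The
printed equation concatenates `(f1 + f2, f1, f2)` and never consumes the
upsampled deep map, contradicting the accompanying prose ("cascaded with
f1 and f3"); the prose variant is the default because it is the one that
actually fuses three scales, and `literal_eq8 = TRUE` restores the
printed form. Downsampling is a stride-2 3×3 convolution (parametric, in
keeping with the re-parameterizable design language); upsampling is
nearest-neighbour and parameter-free.

With three pyramid levels, only the middle level has both a larger and a
smaller neighbour, so the path uses one full three-input Fuse per
direction (top-down and bottom-up) at the middle scale and a two-input
concatenation junction at each extreme; every junction ends in a RepC3
block. This wiring (4 RepC3 blocks, 2 full Fuses) is the package's
reading of the published figure, which does not enumerate its junctions.

RepConv units train as three parallel branches (3×3, 1×1, identity where
shapes allow, each with its frozen batch norm) and fuse algebraically
into a single biased 3×3 convolution for deployment;
`repconv_reparameterize()` performs the fusion and the tests require
eval-mode agreement within 1e-4.

### Batch normalization

All batch norms are *frozen-statistics* norms: the per-channel affine
parameters train while the statistics stay fixed — the convention the
DETR lineage uses for its convolutional backbones (FrozenBatchNorm2d).
This keeps single-image CPU training well-defined (batch statistics of a
batch of one are degenerate) and makes train-form and deploy-form
re-parameterization exactly equivalent. Unit tests pin eval-mode
behavior, and the re-parameterization tests randomize the stored
statistics so the fusion is exercised beyond the identity case.

## Losses and matching

Per image, predictions and truths are matched by an exact Hungarian
assignment (shortest augmenting path, O(n³); verified against brute-force
permutation search) under the DETR-family cost
$2\,c_{\text{class}} + 5\,c_{L1} + 2\,c_{\text{GIoU}}$. The objective is

$$L = L_{VFL} + L_{GIoU} + L_1$$

with unit weights exactly as printed (configurable). VariFocal uses the
IoU-aware classification score: a matched query's target at its truth's
class is the *detached* IoU of its predicted box with that truth;
negatives are weighted $\alpha \hat y^{\gamma}$ with the cited defaults
$\alpha = 0.75, \gamma = 2$ (the source names but never fixes them). The
printed positive branch carries a leading $-y$ factor (rather than $-1$);
it is implemented literally. Sums are divided by the number of positive
matches (clamped to ≥ 1), the DETR-family convention; logs are clipped at
$10^{-7}$.

## Evaluation

`evaluate_detections()` sweeps greedy score-ordered one-to-one matching
(each truth used once, duplicates are false positives) over IoU
thresholds 0.50–0.95. AP is the plain rectangle sum
$\sum_k P(s_k)\,\Delta R(s_k)$ by default — the formula as printed — with
an optional 101-point interpolation mode (`ap_mode = "coco101"`) for
comparability with the common COCO tooling; the test suite checks that
mode against an independently coded interpolated evaluator on random
fixtures. Classes without ground-truth instances are excluded from the
mean rather than scored zero. The dataset-level precision/recall summary
operates at IoU 0.5 and a configurable score cut (default 0.5; the
source tables do not state their operating point). `fps()` implements the
reciprocal timing formula as a utility only.

## Synthetic data

`generate_scene()` renders textured elliptical "animals" of six synthetic
species (distinct aspect ratios, colors, texture frequencies) on a
smooth procedural background, with three difficulty knobs mirroring the
field regimes:

* **occlusion**: vegetation-colored strips cover a requested fraction of
  each animal's pixels (column-cumulative coverage, accurate to a few
  percent; boxes always bound the *pre-occlusion* object);
* **blur**: separable Gaussian with σ in pixels;
* **night**: strong gamma darkening ($x^{1/0.3}$) plus additive Gaussian
  sensor noise (sd 10/255) — an invented stand-in whose parameters live
  in config.

Boxes are 0-based half-open pixel corners internally and COCO
`[x, y, w, h]` on disk. `mosaic()` implements the four-image mosaic
augmentation (probability 0.5 by default) with box rescaling, clipping
and sub-pixel-area dropping; `split_dataset()` produces image-disjoint
7:2:1 splits with largest-remainder rounding, stratified by class-presence
signature.

What passing tests on these scenes does **not** show: real camera-trap
background clutter, pose variation, class imbalance or inter-species
similarity. The generator validates the machinery (geometry, losses,
metrics, training dynamics), not field-level accuracy.

## Calibration of the published model sizes

The source fixes the backbone family and the decoder lineage but not the
widths of the attention/aggregation modules, the feed-forward widths, or
the GELAN hidden width; its parameter counts (15.4 M and 8.2 M for the
two backbone variants with decoder, 18.4 M for the full model, a 46.75 %
reduction) are the only constraints. A one-time sweep over the open
widths produced the calibration recorded in `calibrated_config()`:

* decoder/AIFI: model dim 256, 8 heads, 3 decoder layers, 300 queries,
  feed-forward width 960;
* GELAN terminal stage: transition width 192 (sub-branch width 96), one
  bottleneck per CSP branch;
* aggregation path: width 256, 3 RepConvs per RepC3, RepC3 hidden width
  236; coordinate attention reduced width 8.

At this configuration the exact counts are 15,437,130 / 8,173,130 /
18,437,882 parameters — 15.4, 8.2 and 18.4 M at the printed rounding, and
a 46.75 % reduction computed from the rounded values. The calibration is
checked by the acceptance tests and recomputed from scratch by
`scripts/acceptance.R`.

## Numerical and scale choices

* Initialization is Kaiming-uniform from the R RNG; builders are
  deterministic under a seed. Object-query embeddings use unit-variance
  normal initialization — with a much smaller scale the queries collapse
  onto nearly identical boxes and box regression stalls.
* Toy training uses full-batch AdamW (β = 0.9/0.999, decoupled weight
  decay 1e-4) with 5 % linear warmup and cosine decay to a tenth of the
  peak rate. The end-to-end smoke test — a width-32, 10-query model with
  an 8/16/32/32-channel backbone overfitting five 64×64 single-animal
  scenes for 300 steps at peak rate 1.5e-2 — reaches well under a tenth
  of its initial loss in a few CPU-minutes; these sizes were chosen so
  the whole suite stays comfortably inside a desk-scale CPU budget.
* Matching ties and degenerate cases: empty truth sets yield all-negative
  VariFocal and zero box terms; assignment on rectangular costs pads with
  zero-cost dummies (the padding constant cancels); decoded boxes are
  clamped to image bounds with a minimum side of 1e-3 px.

## Limitations

* CPU-only and toy-scale: the calibrated 18.4 M-parameter model is built
  (for counting) but not trained here.
* The synthetic scenes are deliberately simple; no claim about real
  camera-trap accuracy follows from the green test suite.
* The decoder is a plain query decoder (learned queries, no denoising
  training, no deformable attention, no top-K query selection from
  encoder memory); it is plumbing around the contributed modules, built
  to a documented reference configuration rather than re-derived.
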