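---
title: "Methods: lightweight ghost-convolution detection of sheep aggression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lightweight ghost-convolution detection of sheep aggression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ghostdet)
```

## The problem

In large-scale meat-sheep farming, aggressive interactions (head impacts
between two animals) cause injury and mortality and signal problems with pen
density or feed allocation. Watching surveillance feeds by hand does not
scale, and wearable sensors are costly at flock sizes, so the practical
route is a camera-side object detector that marks aggression events in
still frames. Because such a detector should run on modest edge hardware,
the network must be light: the design below replaces the heavy backbone of
a standard one-stage detector with ghost-module convolutions and keeps
every added information-exchange mechanism parameter-free or nearly so.

`ghostdet` implements this design end to end in R: the building blocks with
exact forward/backward semantics, an analytic cost model, the weather and
geometric augmentations, a synthetic scene generator that stands in for the
(request-only) farm dataset, a trainable anchor-grid detector, and the
evaluation metrics.

## Ghost convolutions

An ordinary convolution producing $n$ output channels from $c$ input
channels with a $k \times k$ kernel on an $h' \times w'$ output grid costs
$n \cdot c \cdot k^2 \cdot h' w'$ multiply-accumulates (MACs). Feature maps
are substantially redundant, so the ghost module spends the full cost on
only $n/s$ "primary" channels and derives the remaining $n(s-1)/s$ channels
by cheap per-channel (depthwise) $d \times d$ linear transforms of the
primary ones. The resulting speedup and compression ratios are

$$
r_s \;=\; \frac{n\,c\,k^2}{\tfrac{n}{s}\,c\,k^2 + \tfrac{n(s-1)}{s}\,d^2}
     \;=\; \frac{s\,c\,k^2}{c\,k^2 + (s-1)\,d^2},
\qquad
r_c \;\approx\; \frac{s\,c}{s + c - 1},
$$

both approaching $s$ for wide layers with $k = d$. The package uses the
depthwise reading of the cheap transform throughout: counting the cheap
operation as dense in $c$ would make $r_s = 1$ at $k = d$, contradicting the
"saves half the computation" behaviour at $s = 2$ that the construction
exists for. With the package defaults ($s = 2$, $d = 3$) each primary map
spawns exactly one cheap map.

```{r}
speedup_ratio(c = 64, n = 128, k = 3, d = 3, s = 2)     # 128/65
compression_ratio(c = 512, n = 512, k = 3, d = 3, s = 2) # ~ 2
```

The partition ratio must divide the output width ($s \mid n$); violating
specs are rejected at construction. For the odd intermediate widths that
arise from bottleneck channel halving (below), the primary width is
`ceiling(n/s)` and the cheap width makes up the remainder, keeping every
block a total function.

### Information exchange: PW- and CS-variants

The ghost output is a concatenation of two populations that never mix. Two
variants restore the exchange:

* **PW-GhostConv** appends a $1\times1$ (pointwise) convolution over all
  $n$ channels — full mixing for an extra $n^2 h' w'$ MACs and $n^2$
  parameters;
* **CS-GhostConv** appends a channel shuffle — the deterministic
  group-interleave permutation (reshape channels to groups $\times$
  $n/\mathrm{groups}$, transpose, flatten) — for exactly zero MACs and zero
  parameters.

"Shuffle" is implemented as the deterministic interleave, not a seeded
random permutation: the operation's purpose is to interleave the primary
and cheap populations, and a deterministic permutation makes the block
testable (the shuffle-then-inverse identity is asserted in the suite). The
group count defaults to 2, aligned with the two-population split; widths
not divisible by the group count (possible only in degenerate odd-width
configurations) fall back to the identity permutation.

### Bottlenecks

The residual bottleneck sandwiches a depthwise $3\times3$ stage (stride
lives here) between two ghost convolutions. The compress-first form halves
the channel count, extracts features at half width, and restores the width
with a second, linear ghost convolution (`max(1, floor(c/2))` on odd
widths). The inverted form — used throughout the backbone — expands to
$2c$ first and compresses last, so the depthwise stage sees
higher-dimensional features; the expansion is fixed at exactly 2 to bound
memory. Both CS-flavoured forms use channel-shuffle ghost convolutions
internally. The shortcut is the identity when the shape is preserved,
otherwise a depthwise-3x3-plus-pointwise projection. With every learnable
weight zeroed and normalisation bypassed, each identity-shortcut bottleneck
reproduces its input bit-exactly — a strong wiring check asserted in the
tests.

Ghost modules inside bottlenecks use $1\times1$ primary kernels with
$d = 3$ cheap transforms (the convention of the lightweight-network family
this block descends from); standalone downsampling blocks use
$k = 3$.

### Normalisation and activation

Each composite block ends with per-channel normalisation and SiLU; the
second ghost convolution of a bottleneck is linear (no activation), and the
shortcut projections are linear too. Normalisation statistics are computed
from the current feature map (instance-style) in both training and
inference, which keeps the two phases identical and is well matched to the
small-batch regime the package trains in; there are no running averages to
desynchronise. Convolutions followed by normalisation carry no bias — the
bias would be cancelled and would break the parameter-count identities.

## The cost model

`count_costs()` reports exact MAC and parameter counts per block and per
network with per-layer breakdowns whose totals are additive.
Conventions: MACs are the primitive unit (FLOPs = 2 MACs on request);
normalisation, activation, shuffle, concatenation and upsampling cost zero
MACs; normalisation scale/shift parameters are counted as zero as well,
since they fold into the preceding convolution at inference — this keeps
the closed-form compression ratio an exact identity against counted
parameters. Two independent oracles guard the algebra: an exhaustive
per-output-element enumeration (`count_macs_enum()`) and an instrumented
forward pass that counts every multiply the runtime kernels issue
(`count_macs_forward()`); the suite requires three-way exact agreement on
every block type.

## The network

`ghost_network_spec()` declares the layer graph: a backbone alternating
standalone PW-GhostConv downsamplers with inverted ghost bottleneck stacks
(stage widths 16-24-40-80-112-160 before the neck, scaled by
`width_multiple`), a top-down/bottom-up feature-pyramid neck built entirely
from CS-GhostConv blocks, and three anchor heads at strides 8/16/32 with
three priors each. Structural rules are enforced by
`validate_network_spec()`: inverted bottlenecks may appear only in the
backbone (their $2c$ expansion in the multi-branch neck would defeat the
memory budget), and the neck never uses a plain ghost convolution when the
cost-free shuffle variant exists. The five ablation variants pairing
standalone and bottleneck-internal flavours are all buildable for
structural comparison, as is a cost-model-only cross-stage-partial DarkNet
backbone that serves as the parameter-count reference; the ghost backbone
undercuts it by an order of magnitude at default widths. All backbone
bottlenecks are inverted by default (config-overridable), and anchor priors
are the standard 640-pixel-reference set — the design source names three
priors per scale but no values.

## Weather augmentation

All augmentations preserve annotations in normalised YOLO coordinates.

**Fog.** For pixel $(i, j)$ (0-based) of an $h \times w$ image with
$\mathrm{size} = \max(h, w)$:
$d = -0.04\sqrt{(i-h/2)^2 + (j-w/2)^2} + \mathrm{size}$,
$t_d = e^{\theta_0 d}$, pixel $\leftarrow$ pixel $\cdot t_d + L(1-t_d)$.
Two notational slips in the published form of this algorithm are resolved
on physical grounds: the column term is $(j - w/2)^2$ — a constant column
term would make fog independent of the column, while a radial field is the
only reading consistent with a single `size` scale — and $\theta_0$ must be
$\le 0$ for $t_d \le 1$ (a fogging effect); positive values are clamped
with a warning. Fog computes in floating point and rounds half-up to
integer intensities. Larger $|\theta_0|$ moves every pixel weakly closer to
$L$ (asserted as a property test).

**Rain and snow.** Sparse seeded noise at a configured density (particles
per megapixel) is shaped by an affine elongation along the fall axis and a
Gaussian blur, rotated to the fall angle, and additively overlaid. The
pipeline order — noise, shape, rotate, overlay — is fixed; the free
parameters are not published, so the presets are chosen once as plausible
defaults and exposed in `precip_params()`: rain = 300 particles/MP,
stretch 8, angle $-75^\circ$, $\sigma = 0.7$; snow = 200 particles/MP,
stretch 2, angle $-5^\circ$, $\sigma = 1.5$; intensity 200 for both. Equal
seeds and parameters give bit-identical output.

**Mirroring and rotation-scaling.** Horizontal, vertical and diagonal
mirrors co-transform boxes by coordinate reflection and are exact
involutions. Rotation-scaling maps boxes as the axis-aligned envelope of
their four transformed corners, clipped to the frame; a box retaining less
than 10% of its transformed envelope area is dropped (the source never
states how labels were handled under rotation — envelope-plus-drop is this
package's choice, keeping labels meaningful without inventing occluded
geometry). Image resampling is nearest-neighbour with neutral-grey fill.

`augment_dataset()` augments a seeded `floor(fraction * N)` subset (default
half) with one uniformly chosen operation per image, replacing originals or
keeping them alongside. A standalone Gaussian blur is provided but is not
part of the default menu, since it is primarily a particle-shaping step in
the rain/snow pipeline.

## Synthetic scenes

`generate_scene()` emulates overhead barn footage: a textured floor,
ellipse-bodied sheep (light fleece, darker head blob at the body tip), and
aggression events rendered as two sheep posed head-to-head along a shared
axis with colliding head blobs — the "head impact" signature. Each event
yields one box of the single class `aggression` spanning the contact pair:
event-level boxes, not per-animal ones, matching single-class event
labelling. Placement is rejection-sampled with bounded retries; dim
lighting (5% of scenes by default, mirroring the share of non-daytime
recordings) darkens and desaturates. `generate_dataset()` writes the
standard `images/{train,val,test}` + `labels/` layout with a seeded-shuffle
contiguous split at 6:2:2 under largest-remainder rounding (ties broken
train > val > test) and a manifest with class balance, box-size statistics
and a checksum.

What the generator does *not* emulate: occlusion between animals, crowding
beyond mild density, motion blur, perspective distortion, and the visual
ambiguity between aggression and benign head-proximity (courtship,
feeding). Tests passing on synthetic scenes therefore validate the
*mechanics* — shapes, costs, gradients, convergence, metric arithmetic —
not field accuracy on real footage.

## Detector training and inference

Decoding follows the anchor-grid convention: per cell and prior, centre
$(2\sigma(t) - 0.5 + \mathrm{cell}) \cdot \mathrm{stride}$, extent
$(2\sigma(t))^2 \cdot \mathrm{anchor}$, score = objectness $\times$ class
probability; scores below the confidence threshold are removed, and greedy
per-class non-maximum suppression (stable descending-confidence order, so
equal-confidence ties resolve by input order) prunes overlaps at IoU
$\ge$ 0.45. Default inference thresholds are confidence 0.25 and NMS IoU
0.45, both arguments.

Training uses the reference recipe — SGD, initial learning rate 0.01,
batch size 4, 300 epochs, no pretraining — with a complete-IoU box loss
(analytic gradient, verified against finite differences with the usual
constant-$\alpha$ convention) and binary cross-entropy objectness. Truths
are assigned to all anchors within an extent ratio of 4 at the centre cell
and its two nearest neighbour cells, with a best-anchor fallback so every
truth trains something.

Three loss-design choices depart from the large-scale convention because
this package's training regime is a few hundred SGD steps, not tens of
thousands, and the loss source design is silent on these details:

* **hard objectness targets** (1 at assigned cells) rather than IoU-valued
  soft targets — soft targets carry an entropy floor that dominates the
  total loss long before convergence at this scale;
* **positive/negative-balanced objectness BCE** — positives and negatives
  are averaged within their own groups, so a handful of assigned cells is
  not diluted by thousands of empty ones;
* **box gain 0.5** (with objectness gain 1, class gain 0.5) — the
  conventional 0.05 is calibrated to ~60k-step schedules and leaves box
  regression far from convergence within the package's test budget.

The class channel is trained (target 1 at positives) for any class count,
so the detection score reduces to calibrated objectness in the single-class
case. All randomness — weight initialisation, data order, scene content —
flows from explicit integer seeds; two runs with the same seed produce
identical logs.

## Numerical choices

* Degenerate metric denominators (no predictions, no truths) define the
  affected metric as 0 and set a flag rather than erroring.
* Average precision integrates the all-points precision envelope over
  recall (not the 11-point approximation); mAP averages AP over classes at
  matching IoU 0.5 (flag-overridable). The suite checks the implementation
  against a brute-force all-thresholds enumeration to $10^{-9}$.
* Greedy matching consumes each truth at most once, in descending
  prediction confidence; `TP + FN` equals the truth count per class by
  construction.
* Fog, scene rendering and precipitation round half-up and clip to
  $[0, 255]$ at the last step only.
* The zero-area-box IoU is defined as 0 with a warning.

## Problem sizes

The test suite exercises full fidelity at reduced scale, chosen once as
the package's own desk-scale conditions: block-level checks run on
4-16-channel maps; cost identities on a ~200-spec grid; the end-to-end
check trains a `width_multiple = 0.5` network on eight 160-pixel synthetic
scenes for 150 epochs (about 300 SGD steps, a few minutes on one CPU) and
then requires the final loss below 20% of the epoch-1 loss and at least 7
of 8 ground-truth boxes recovered at IoU $\ge$ 0.5 on the training scenes.
This is an overfitting smoke test: it demonstrates that the assembled
network, loss, gradients and decoder can jointly drive training to
convergence, not that the model generalises.

## Limitations

* Absolute GFLOP totals of the published full-resolution network are not
  reproduced: the exact layer list of the original is not enumerable from
  its description, so all cost claims are relative or structural (the
  zero-cost shuffle identity, the backbone-versus-reference comparison).
* Real-data accuracy (P/R/mAP in the mid-90s on farm footage) is out of
  reach by construction — the farm dataset is available only on request —
  and nothing in the synthetic results should be read as predicting it.
* The video (temporal) detection pathway is out of scope; this package
  covers the still-image model only.
* Training is single-threaded CPU R; it is meant for the desk-scale
  regimes above, not for production training runs.
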