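---
title: "Lesion-wise evaluation and DRAU-Net: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion-wise evaluation and DRAU-Net: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(draunet)
```

## Why a lesion-wise metric

Brain metastases are typically multiple and small. A segmentation model
that recovers one large lesion perfectly and misses four tiny ones can
still post an excellent global Dice score, because global Dice pools
pixels: the large lesion dominates the numerator and denominator alike.
Clinically the opposite weighting is wanted — every missed metastasis is
a missed treatment target.

The multi-objective segmentation integrity metric (MSIM) implemented here
scores lesions, not pixels. For a ground-truth mask and a predicted mask:

1. **Component extraction.** Both masks are decomposed into connected
   components (8-connectivity in 2-D, 26 in 3-D by default — metastases
   are compact blobs, so the fullest neighborhood is the natural choice;
   both are configurable).
2. **Filtering.** Ground-truth components smaller than `delta` pixels are
   discarded, as are (optionally) components that do not overlap a
   tumor-core mask. The prediction is deliberately *not* area-filtered:
   spurious small predicted components cost nothing here by design, since
   MSIM measures integrity of recall over true lesions, not precision.
3. **Smoothing.** Each retained ground-truth component is closed
   morphologically (dilation then erosion, 3x3 cross, one iteration), so
   pinholes and ragged annotation boundaries do not depress per-lesion
   overlap. The grid is padded internally before closing so components at
   the image border are not eroded away.
4. **Matching.** Ground-truth components are visited largest first; each
   is paired with the not-yet-consumed predicted component maximizing the
   per-lesion Dice over its pixel set. A pairing whose Dice is *strictly*
   greater than `theta` (default 0.7) counts as a success and consumes
   the predicted component; a failed attempt leaves the prediction
   available for smaller lesions.
5. **Score.** `MSIM = successes / u`, with `u` the number of retained
   ground-truth lesions; undefined (`NA`) when `u = 0`.

With `k` equal, well-separated lesions of which one is missed, MSIM is
exactly `(k-1)/k` while global Dice is `2(k-1)/(2k-1) > (k-1)/k` — the
quantitative form of the under-penalization argument, and one of the
package's acceptance properties.

### Design choices in the matcher

The defining procedure sorts components by size and compares "in pairs"
without pinning down the assignment rule. We use deterministic
largest-first greedy assignment with one-to-one consumption, with ties in
Dice resolved toward the larger predicted component and then the lower
component id. The test suite validates this choice against an exhaustive
maximum-matching reference (Kuhn's algorithm on the success graph) over
hundreds of randomized phantom pairs: greedy can never exceed the
optimum (it is itself an injective pairing), and it must agree whenever
no component has more than one success-capable partner. Because a
success needs Dice > 0.7, and two disjoint predictions cannot both
overlap one lesion that strongly, ambiguous instances are rare in
practice; in the randomized families we generate, greedy has agreed with
the optimum on every instance.

Two further conventions worth stating explicitly:

* **`delta` has no canonical value.** The area-filter threshold is part
  of the metric's definition but no reference value exists; the default
  is 5 pixels (enough to drop annotation specks at BraTS-like resolution
  without touching genuine small metastases). Every report carries the
  `delta` used, and the command-line tool prints it on each run —
  published MSIM values are only comparable at equal `delta`.
* **Boundary case.** `Dice == theta` is a failure; the success test is a
  strict inequality.
* **Dataset aggregation** is micro-averaged (summed successes over summed
  lesion counts across cases), reading the metric's double summation
  literally; the per-case mean (macro) is reported alongside since the
  two differ whenever lesion counts vary across cases.

## Global metrics

Dice, sensitivity, PPV and Jaccard are computed from pixel confusion
counts per binary class mask. Zero-denominator cases return `NA` rather
than 0 or 1: an empty ground truth makes sensitivity meaningless rather
than bad, and a lesion-free slice scored against an empty prediction
should not inflate dataset averages with free perfect scores. Dataset
summaries average defined values only. The identity
`dice = 2 J / (1 + J)` and the duality
`sensitivity(pred, gt) = ppv(gt, pred)` are enforced by property tests.

## The segmentation network

DRAU-Net is a U-Net-shaped encoder-decoder operating on 2-channel
(post-contrast T1, T2-FLAIR) slices:

* **Encoder** (4 levels by default): two 3x3 conv + BN + ReLU layers,
  then a **DResConv** residual block — a 3x3 convolution at dilation 1
  followed by a 3x3 convolution whose dilation equals the level index,
  added back to the block input. The dilated branch widens the receptive
  field (3 + 2i pixels per axis at dilation i) without extra parameters.
  2x2 max pooling downsamples between levels.
* **Decoder**: kernel-2 stride-2 transposed convolution doubles the
  resolution (a stride-1 1x1 transposed convolution cannot change
  resolution, so the stated purpose dictates this form); the skip feature
  passes through **MBWA** attention; the two are concatenated, fused by a
  1x1 convolution, and refined by a conv block plus DResConv.
* **MBWA** (multi-branch weighted attention): the feature map is
  average-pooled along each spatial axis; the row and column descriptors
  are concatenated and mixed by a shared channel-reducing 1x1 convolution
  (+ BN + ReLU), split back, restored to full channel width by two 1x1
  convolutions (+ BN + sigmoid), and applied as
  `O = I * (w_rows + w_cols)`. Both weight fields lie in (0, 1), so
  `|O| <= 2 |I|` elementwise — a bound the tests check. Axis-wise pooling
  preserves positional information along the complementary axis, which is
  what lets the gate localize small lesions.
* **Heads**: a final 1x1 convolution with per-channel sigmoid produces
  two independent binary maps (whole tumor, tumor core). The two labels
  can overlap, which rules out softmax.

Choices the architecture description leaves open, fixed here and exposed
in `network_config()`: channel widths `base_width * 2^(level-1)`
(32, 64, 128, 256 with a 512-channel bottleneck by default), max-pool
downsampling, attention channel reduction 8 (floored at 8 channels),
He-uniform initialisation. The default network has 10,328,386 trainable
parameters; the test suite pins this against a closed-form layer-algebra
count.

The numerical engine is written in this package (R plus one
Rcpp/RcppArmadillo kernel for the dilated convolution), with feature maps
as dense `(H, W, C, N)` arrays and an internal channels-last layout that
makes every matricisation a zero-copy reshape. Backpropagation is
implemented analytically per layer and validated end-to-end against
central finite differences (relative error below 1e-3 with a 1e-4 floor
at near-zero gradients; convolution biases feeding batch norm have
exactly zero gradient, which the check confirms).

## Loss

`loss = alpha * soft_dice + beta * bce` with `alpha = 0.7`,
`beta = 0.3`. The defining equation places `alpha` on the Dice term even
though the accompanying prose lists the weights in the opposite order;
the equation wins, and both weights are configurable. Soft Dice is
computed per output channel per sample and averaged (smoothing constant
1e-5 keeps empty-mask slabs finite); BCE is averaged over all elements
with probabilities clipped at 1e-7. The analytic gradient of the combined
loss is part of the public API and is finite-difference tested.

## Synthetic phantoms

The phantom generator makes two-channel slices over a circular brain
region (radius 0.45 of the grid) containing 1-6 disc lesions with
whole-tumor radius 2-12 px drawn log-uniformly — deliberately skewed
toward the small-metastasis regime that motivates lesion-wise scoring —
and a concentric core at half the radius. Channel 1 brightens at the
core (T1-contrast-like), channel 2 over the whole lesion (FLAIR-like);
Gaussian noise (sd 0.1) is added inside the brain. Placement is
rejection-sampled so lesion boundaries stay at least `min_separation`
(default 3) pixels apart, guaranteeing that the component count equals
the catalogue length.

What the phantoms do *not* emulate: anatomical texture, partial-volume
edges, registration error, irregular lesion morphology, and
inter-annotator noise. Tests passing on phantoms therefore establish the
correctness of the algorithms (metric semantics, gradient flow, pipeline
plumbing), not clinical segmentation accuracy; the reference results on
real BraTS and clinical data require GPU-scale training outside this
package's scope.

## Problem sizes and numerical conventions

* The overfit check trains the default architecture at `base_width = 8`
  on eight 64x64 phantom slices with the reference optimizer settings
  (Adam, learning rate 3e-4, batch 8) and reaches whole-tumor Dice > 0.9
  in about 45 epochs; these sizes keep a full CPU run under a minute
  while exercising every layer at full depth.
* Batch normalization uses biased variance and momentum 0.1 running
  statistics; evaluation mode uses the running statistics.
* Max-pool ties resolve to the first window position; component labels
  are assigned in order of smallest linear index, so all results are
  exactly reproducible for fixed seeds.
* Binarization of sigmoid outputs uses threshold 0.5 (configurable).
* Z-score normalization uses population (1/n) standard deviation over
  nonzero voxels only — BraTS volumes are skull-stripped, so including
  background zeros would bias the statistics. A constant brain region is
  an error, not a silent zero-division.
* The whole-tumor regrouping of BraTS2023 labels is label 2 only, exactly
  as specified for this pipeline, although it differs from the
  conventional BraTS union; `orthodox_wt = TRUE` restores the union.
  Whether the narrower definition is intended or a typo cannot be
  resolved from the description, so the printed form is the default.

## Known limitations

* 2-D slices only; the network has no 3-D convolution path (MSIM itself
  handles 3-D volumes in both per-volume and per-slice modes).
* The training loop is plain full-precision CPU Adam without
  augmentation, schedules, or early stopping beyond an optional target
  Dice — adequate for phantom-scale experiments, not for BraTS-scale
  training.
* Greedy matching is validated against the exhaustive optimum empirically,
  not proven equivalent; on adversarially overlapping predictions the
  greedy score may fall below the optimum (never above).
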