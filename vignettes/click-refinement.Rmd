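---
title: "Interactive lesion segmentation with click-guided residual refinement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interactive lesion segmentation with click-guided residual refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

ClickSeg implements a two-stage interactive segmentation pipeline for skin
lesions in dermoscopy images.

**Stage 1 (SBox).** The user draws a loose *surrounding box* around the
lesion. The box crops the region of interest, which is resized to a square
crop and segmented by a fully convolutional network: a shared encoder yields
a shallow stride-4 feature grid and a deep stride-16 grid; a global-context
extractor enriches the deep grid; the decoding head reduces the shallow
channels by 1×1 convolution, bilinearly upsamples the context features ×4,
concatenates, refines with a 3×3 convolution and projects to one logit
channel, upsampled ×4 back to crop resolution. Training simulates the
looseness of user boxes by jittering each edge of the ground-truth bounding
box independently and uniformly by up to 30 px.

**Stage 2 (Click).** Where the coarse result is wrong, the user clicks:
*positive* clicks on wrongly excluded pixels, *negative* clicks on wrongly
included ones. The click sets $S^1$ (positive) and $S^2$ (negative) are
encoded as two Gaussian distance channels

$$G^{1}_{(m,n)} = \max_{s_{i,j} \in S^1} e^{-4\left((m-i)^2+(n-j)^2\right)/R^2},
\qquad
G^{2}_{(m,n)} = \max_{s_{i,j} \in S^2} e^{-4\left((m-i)^2+(n-j)^2\right)/R^2},$$

where the radius $R$ controls each click's area of influence. The refinement
head consumes the context features cached from the coarse pass (never the raw
image, and never a second encoder pass) together with the two guidance
channels, and emits refinement logits $C$. A polarity-blind weight map at a
much larger radius $R_w$,

$$W_{(m,n)} = \sum_{s_{i,j} \in S^1 \cup S^2}
e^{-4\left((m-i)^2+(n-j)^2\right)/R_w^2},$$

localizes where refinement may act, and the final result is the residual
fusion

$$F = W \ast C + B$$

(elementwise product and sum). Where no clicks were placed ($W = 0$) the
fused output is *bit-identical* to the coarse output; each click licenses an
additive correction over a broad neighbourhood.

**Metrics.** Accuracy, sensitivity, specificity, Dice and IoU are computed
from pixel confusion counts. Any ratio with a zero denominator is reported as
`NA`, never silently as 0, so dataset means are not corrupted.

# Design choices in detail

Several aspects of the pipeline are genuinely open; the package resolves them
as follows.

**Domain of the fusion rule.** $B$, $C$ and $F$ are treated as logits
(pre-sigmoid maps), binarized at 0. In the logit domain $W \ast C$ is a true
additive residual and fusion is closed under addition; probabilities, when
needed, are `sigmoid(F)`.

**Gaussian radii.** Defaults are $R = 40$ px and $R_w = 3R$ at a 256 px
crop, scaled proportionally to other crop sizes (15 px and 45 px at the
96 px desk-scale crop). The ratio matters more than the absolute value: $R$
should cover a typical error region, while $R_w$ must be "much larger" so a
single click can license correction across a whole mistaken blob. Both are
exposed in `trainConfig()` and the session/evaluation functions. $W$ is not
clamped or normalized: the Click stage is trained through the fused loss, so
it absorbs the scale of $W$.

**Evaluation region.** All metrics are computed over the cropped region of
interest at crop resolution — the frame both stages actually operate in.
Full-frame masks produced by `sessionMask()` are background outside the box
by construction.

**Coordinates.** Everything is (row, col), 0-based; boxes are half-open.
Clicks are stored in crop coordinates, the frame both networks see.

**Click simulation.** Positive clicks are sampled uniformly without
replacement from the false-negative set, negative clicks from the
false-positive set. A total budget is split between the two sets
proportionally to their areas, ties resolved toward positive clicks, and
leftover budget moves to the other set when one is exhausted. During
refinement training, clicks are resampled on every pass (rather than fixed
per object), which exposes the head to more interaction diversity at no
cost. Degenerate jittered boxes are resampled rather than clamped, which
preserves the uniform-offset model of user looseness.

**Networks.** The reference design builds the coarse stage on a large
pretrained backbone; this package substitutes a compact four-stage stride-2
encoder (about 29k parameters at the default widths) with the same two-grid
feature contract (strides 4 and 16). The framework under test — interaction
simulation, guidance encoding, residual fusion, two-stage training — is
independent of backbone capacity, and the compact encoder trains on a single
CPU in minutes. Any backbone reproducing the two-grid contract can be
swapped in behind `encoderForward()`. The refinement head consumes the
*context-extracted* deep features (post-context, pre-decoder), cached from
the coarse pass, and deliberately not the shallow features: clicks are
semantically and spatially informative at the abstraction level of deep
features. Guidance maps are computed at crop resolution and bilinearly
downsampled to the feature grid, preserving sub-stride click positions.
Three global-context extractors are interchangeable behind one interface for
the ablation harness: `aspp` (parallel 3×3 convolutions at dilation rates
1/2/4 plus a global-average branch, concatenated and projected), `psp`
(average pooling to 1/2/3/6 pyramid grids, projected, upsampled,
concatenated with the input, projected), and `naive` (a single 3×3
convolution).

**Training.** Both stages use pixel-wise binary cross-entropy (the loss is
not prescribed by the design; BCE is the standard choice for binary
segmentation heads), momentum SGD (base learning rate 0.01, momentum 0.9,
weight decay 5e-4, batch size 8) under the polynomial schedule
$\mathrm{lr} = \mathrm{base} \cdot (1-\mathrm{iter}/\mathrm{max\_iter})^{0.9}$
stepped per batch. The refinement stage trains only on *hard examples* —
objects whose coarse IoU falls below 0.9 — with base learning rate 0.1 and
the coarse stage frozen (the two stages are deliberately decoupled; a joint
fine-tune is intentionally not performed). Box jitter is applied in
original-image pixels before the crop is resized. All training is
deterministic given the seed: fixed shuffling, click sampling and jitter
streams, so two runs produce bit-identical parameters.

# The synthetic data generator

Real dermoscopy archives cannot be bundled, so the generator emulates the
features of dermoscopy that matter to this pipeline:

* a skin-toned background (base RGB ≈ (205, 160, 140), jittered per image)
  with a smooth random shading gradient and Gaussian sensor noise (sd 8);
* one star-convex lesion blob, radius between 1/6 and 1/3 of the image side,
  with an irregular boundary built from four radial harmonics (the $k$-th
  perturbing the radius by up to $0.25/k$), filled darker than skin by a
  per-image contrast drawn between 45% and 100% of 70 intensity units —
  dermoscopic lesions range from faint to near-black, and the faint end is
  what produces imperfect coarse segmentations;
* the ground-truth mask is the *exact analytic* blob interior, computed
  before the image is blurred (σ = 2 px), mimicking crisp expert annotation
  over soft optical boundaries;
* with probability 0.5, one distractor artifact: a lesion-toned blot placed
  adjacent to (but never overlapping) the lesion, or a hair-like dark
  polyline across the frame, clipped to stay out of the mask. Distractors
  are designed to fool an intensity-driven segmenter into false positives —
  exactly the mistake class click refinement exists to fix — while leaving
  the ground truth untouched.

Star-convex radial-harmonic blobs were chosen over spline blobs because they
guarantee a single connected component and admit an exact interior test for
the mask. What the generator does *not* emulate: real pigment texture,
vignetting, colour calibration differences, multiple lesions, or ambiguous
boundaries where even expert annotations disagree. Passing the packaged
experiments therefore demonstrates that the pipeline's mechanics work
end-to-end — that the coarse stage learns, that hard examples exist, and
that clicks reliably improve them — not that the numbers transfer to
clinical imagery.

# The desk-scale experiment

The packaged experiment (also what `scripts/acceptance.R` reruns) uses 300
synthetic 96×96 samples with distractors on half (200 train / 100 held out),
the default `aspp` context, 20 coarse epochs, hard-example mining at
IoU < 0.9 and 10 refinement epochs — about two minutes on one CPU. Under
these conditions the coarse stage reaches a held-out mean IoU well above
0.9, a hard subpopulation of roughly 10% of training objects remains, and
two simulated clicks raise the mean IoU on that hard subset by more than one
IoU point. The ablation harness trains all three context extractors under
identical seeds on a 100-sample fixture at reduced epochs — enough to
compare them mechanically, not enough to rank them definitively.

The unit-test fixture is smaller still (40 samples at 64 px, 48 px crops,
8 epochs); it exists to give tests realistic trained predictions quickly,
not to demonstrate accuracy.

# Numerical and degenerate-input conventions

* Binarization is a strict threshold (`pixel > t`), default 0 in the logit
  domain; an all-zero logit map yields an all-background mask.
* Gaussian kernels are never truncated; distances are exact squared
  Euclidean distances in pixel units.
* Click sets may be empty anywhere; empty guidance and weight maps are
  all-zero and fusion degenerates to the coarse result exactly.
* A click budget larger than an error set returns every pixel of the set.
* Masks are resampled bilinearly and re-thresholded at 0.5, so resized
  ground truth stays crisp 0/1.
* `mineHardExamples()` and all evaluation defaults use the un-jittered tight
  box, making reports deterministic; training-style jitter can be enabled
  for robustness studies.
* Censored samples in `clicksToTarget()` (still below target at the click
  budget) are flagged and reported, never silently averaged away.

# Known limitations

* The compact encoder saturates well below what a pretrained backbone
  reaches on real data; absolute IoUs on real dermoscopy require swapping in
  a stronger encoder behind the two-grid contract.
* The refinement head operates at the stride-16 grid, so a single click
  cannot sharpen fine boundary detail; it excels at removing or restoring
  blob-scale regions, which is what the weight map licenses.
* Interaction simulation samples clicks uniformly from error sets; real
  users prefer error-region centres, so simulated clicks are, if anything, a
  harder condition.
* One lesion per image; multi-lesion scenes and scribble or extreme-point
  interactions are out of scope.
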