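---
title: "Weakly supervised attention-guided slice classification: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised attention-guided slice classification: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains what `wsattn` computes, the assumptions behind each
stage, the tunable parameters and their defaults, what the synthetic data
generator does and does not emulate, and the design decisions made where
the method description leaves latitude.

## The problem

Classifying brain-MRI slices as diseased or normal from image-level labels
only is a fine-grained recognition problem: the two classes differ in a
small, spatially localized region, and the labeled datasets are small. The
pipeline here combines three ideas: (i) let the network produce explicit
*attention maps* alongside features; (ii) use those maps to synthesize
extra training views (zoomed-in crops of the attended region, and images
with the attended region erased) so supervision is recycled into
localization; (iii) gate the backbone's residual blocks by channel and
spatial attention so feature extraction itself concentrates on
discriminative structure.

## Slice selection and partitioning

3D scans contain many near-empty slices. Each axial slice is quantized to
`G = 256` gray levels by per-volume min–max scaling and scored by the
Shannon entropy of its empirical gray-level histogram (in bits, so
`0 <= H <= log2(G)`); the top `k = 32` slices per scan are retained,
sorted entropy-descending with ties broken by ascending slice index. The
logarithm base and the tie-break are our choices — base 2 makes the bound
interpretable, and a stable tie-break keeps ranking deterministic.

The dataset is split per class into train/validation/test with weights
8:1:1 (`floor(n * r)` for train and validation, remainder to test), which
maps 2560 slices per class to 2048/256/256. The split operates at slice
level by default, matching the study design it mirrors; note that
slice-level splitting lets slices of one subject appear on both sides of
the partition, so for subject-safe evaluation the caller should pass
subject identifiers (one id per subject, then expand) — `splitDataset`
only guarantees stratification and determinism over whatever ids it is
given.

## The model

**Backbone.** A residual bottleneck network (`"resnet50"`: the standard
3+4+6+3 stage layout; `"tiny"`: two blocks, < 100k parameters, for
CPU-scale work). Every bottleneck computes a residual through
1×1 → 3×3 → 1×1 convolutions with batch normalization and ReLU, then gates
it:

- channel gate: `Mc = sigmoid(MLP(avgpool(F)) + MLP(maxpool(F)))`, one
  shared bias-free MLP with hidden width `C / r` (reduction `r = 16`,
  clipped to keep at least one hidden unit) and ReLU hidden activation;
- spatial gate: the channel-wise mean and max maps are stacked and
  convolved 7×7 (padding 3 preserves the spatial size) to a single map,
  then `Ms = sigmoid(...)`;
- the gated residual is added to the (possibly projected) shortcut:
  `Xbar = X + F''`. We place the gates after the third convolution and
  before the addition — the only placement consistent with the residual
  fusion equations — and we do **not** apply an activation after the
  addition, so a zero residual reproduces the input exactly.

Since both gates lie strictly in (0, 1), gating never increases the
magnitude of any activation, and the identity branch guarantees gradient
flow (both properties are asserted in the tests, the latter by finite
differences).

**Attention head and pooling.** A 1×1 convolution maps the M feature
channels to `N` attention maps with a ReLU, making every attention value
nonnegative — a requirement for the threshold masks below to be
meaningful. `N = 32` by default (4 in the CPU-scale experiments). Bilinear
attention pooling forms `P[i, ] = GAP(A_i * F)`, an N×M matrix; the
classifier flattens `P`, L2-normalizes it (stabilizing training across
attention scales), and applies a linear softmax.

**Augmentation.** For each training image one attention map is drawn
uniformly (a single draw shared by crop and drop; independent draws are
available via a flag). The map is min–max normalized to [0, 1] — a
constant map normalizes to all zeros, i.e. "nothing attended". The crop
mask marks entries strictly above `theta_c`, its minimal bounding box is
mapped proportionally to image coordinates and bilinearly enlarged to the
input size; the drop mask zeroes entries strictly above `theta_d` after
nearest-neighbor upsampling. Defaults `theta_c = theta_d = 0.5`; an
optional mode samples both uniformly from [0.4, 0.6] per batch. If no
entry exceeds the threshold the full-image box is used (with a warning at
the user-facing level), so training never stalls on a flat map. Mask
construction is treated as non-differentiable: gradients reach the
attention head only through the forward losses, not through the masks.

**Losses and centers.** Each step forwards the raw, cropped and dropped
batches and minimizes `(ce_raw + ce_crop + ce_drop) / 3 + lambda * LA`
with `lambda = 1`. `LA = sum_i ||f_i - c_i||^2` with centers updated by
`c_i <- c_i + beta * (f_i - c_i)`, `beta = 0.05`, as plain non-trainable
state. Two notes on this term:

- it is computed on the raw pass only, keeping the centers consistent
  with un-augmented parts;
- it is computed on the **L2-normalized** part features — the same
  representation the classifier consumes. Applied to raw pooled features
  with zero-initialized centers, the penalty admits a degenerate solution
  in which all attention maps shrink to zero (the centers chase the
  shrinking features downward and the classifier input dies); we observed
  exactly this collapse. On the normalized features the loss penalizes
  only the *direction* of each part feature relative to its moving
  center, which is the intended consistency effect.

**Optimizer.** Momentum SGD (momentum 0.9) with cosine learning-rate decay
over epochs. The package default is `lr = 0.001`, a fine-tuning scale; the
synthetic recovery experiment trains the tiny variant from scratch and
uses `lr = 0.03`, the standard scale for small CNNs with batch
normalization trained from random initialization. Both are plain
configuration values. Training aborts with a diagnostic (activation norms)
on a non-finite loss rather than continuing silently.

**Inference.** Coarse probability from the raw image; fine probability
from a second forward pass on the crop defined by the summed, normalized
attention maps at `theta_test = 0.1` (no test-time threshold is prescribed
by the method; 0.1 keeps the crop generous, and a flat attention map falls
back to the full image so the fine pass degrades gracefully to the coarse
one). The final probability is the average `(Pc + Pf) / 2`; the decision
is its argmax with ties resolved toward the negative class, the
conservative choice for screening. Metrics are the five confusion-matrix
quantities; a metric with a zero denominator is reported as `NA` and
flagged, never as 0.

## Implementation notes

No deep-learning framework is used: convolutions are computed by im2col
lowering onto BLAS matrix multiplication, and every layer's backward pass
(convolution, batch normalization, max pooling, both attention gates,
pooling, normalization, softmax) is derived analytically. The test suite
verifies all of them against central finite differences at tolerances
around 1e-6 on random instances, and verifies forward semantics against
naive triple-loop oracles. Numerical guards: the L2 normalization treats
vectors below 1e-12 as zero (with zero gradient); softmax subtracts the
row maximum; cross-entropy clamps probabilities at 1e-12; max-pool and
channel/spatial max operations break ties by first index, keeping results
deterministic.

All randomness flows from a single seed through named substreams (data,
init, split, volume, augment, epoch), so changing how many random numbers
one stage consumes does not perturb the others, and repeated runs are
bitwise identical. RNG state of the calling session is always restored.

## The synthetic generator

Synthetic slices emulate the geometry of the task, not brain anatomy: a
deterministic smooth elliptical background, additive Gaussian pixel noise
(sd 0.05 by default, clipped to [0, 1], quantized to 256 levels), and — in
the positive class only — a disk of extra intensity (radius 4 px, contrast
0.5 by default) at a class-consistent anchor jittered uniformly by ±10% of
the image size, so a classifier must localize the lesion rather than
memorize coordinates. Lesion centers are recorded as ground truth.
Synthetic volumes interleave textured (high-entropy) and constant
(zero-entropy) slices with the textured indices recorded.

What passing tests on this data shows: the optimization works end to end,
the attention localizes a planted signal (the test-time crop box overlaps
the lesion), augmentation and fusion do not degrade a learnable problem.
What it does not show: robustness to anatomy, registration error,
scanner effects, subject-level correlation, or class imbalance — real MRI
claims require real MRI.

## Experiment scales

The bundled experiments are sized for a single CPU: the recovery study
uses 32×32 slices, 300 per class split 4:1:1 (400 train / 100 validation /
100 test), the tiny backbone with 4 attention maps, batch 16, 10 epochs.
Under those conditions training plus the two-pass evaluation completes in
well under a minute and reaches coarse test accuracy ≥ 0.9 (typically
0.98–1.0), with fused accuracy at or slightly above coarse.

## Known limitations

- The ResNet50-shaped variant is structurally faithful but impractical to
  train in pure R; it exists for architecture parity and checkpoint
  loading, and `pretrained = TRUE` is an explicit error because no weight
  source ships with the package.
- Only binary classification is implemented (the multiclass extension
  would change the head and metrics only).
- Slice-level splitting can leak subjects across partitions; pass
  subject-level ids to `splitDataset` when that matters.
- The augmentation library is deliberately minimal: no photometric or
  geometric augmentations beyond the attention-guided crop and drop,
  which are the point of the method.
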