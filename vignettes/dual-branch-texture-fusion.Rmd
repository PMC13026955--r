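---
title: "Dual-branch RGB–texture fusion: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-branch RGB–texture fusion: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`lbpfuse` implements a mid-level fusion classifier for small multi-class
clinical image datasets. Two branches process every image:

* an **RGB branch** — a pretrained-style convolutional backbone whose feature
  maps are globally average-pooled to a fixed-length vector (1792-d under the
  EfficientNetV2-S feature contract);
* a **texture branch** — the image is converted to grayscale, transformed
  into a uniform Local Binary Pattern (LBP) code image (P = 8, R = 1,
  59 bins), rescaled to an 8-bit plane, and fed through a small CNN:
  three blocks of (3×3 conv, padding 1 → batch norm → ReLU → 2×2 max pool)
  widening 1 → 16 → 32 → 64, a squeeze-and-excitation (SE) gate
  (64 → 4 → 64, sigmoid), and adaptive average pooling to 4×4, flattened to
  a 1024-d vector.

The two vectors are concatenated (2816-d under the defaults) and classified
by a single affine head. Mid-level (feature-level) fusion lets the colour
pathway and the texture pathway specialise and the head weigh them jointly.

The LBP code at a pixel thresholds the 8 ring neighbours against the centre,
`sum_p s(g_p - g_c) 2^p` with `s(x) = 1` for `x >= 0`, and maps raw codes
with at most two circular bit transitions to 58 distinct bins, all others to
one miscellaneous bin. Two facts matter for everything downstream: codes are
**invariant to intensity shifts** (only signs of differences enter) and
**insensitive to noise amplitude on flat regions** (iid noise of any
standard deviation produces the same sign-pattern distribution). The
59-bin mapping is the non-rotation-invariant uniform variant — the only
uniform mapping with 59 patterns at P = 8; the rotation-invariant one has
10.

The SE block computes the spatial mean of every channel (squeeze), passes it
through a bottleneck MLP with ReLU and a sigmoid gate (excitation), and
rescales channels by the resulting weights in (0, 1). Both bottleneck layers
carry biases, initialised to zero, so a freshly zeroed block scales inputs
by exactly one half — a useful exactness anchor for tests.

## Geometry and numerical choices

* **LBP ring**: the 8 integer-offset neighbours of the 3×3 square, clockwise
  from the top-left, bit weight `2^p`. No sub-pixel interpolation at R = 1;
  the 59-bin pattern count is unaffected by sampling geometry.
* **Border handling**: replicate padding before coding, so the code image
  has the input's dimensions and both branches stay aligned at 224×224.
* **Ties**: `s(0) = 1`, taken literally from the sign function's `x >= 0`.
* **Grayscale**: ITU-R BT.601 luma (0.299, 0.587, 0.114), rounded half up.
* **Code rescaling**: bin `b` maps to `round_half_up(b * 255 / 58)` —
  injective and order-preserving over the 59 bins; the network consumes the
  plane divided by 255 into [0, 1]. Only the RGB planes receive the ImageNet
  mean/sd standardisation; the texture plane is already bounded and carries
  no pretrained-weight compatibility constraint.
* **Batch norm**: biased variance for normalisation, unbiased for the
  running statistics, momentum 0.1, eps 1e-5; evaluation uses running
  statistics.
* **Pooling ties**: max-pool takes the first maximum in scan order;
  adaptive pooling uses floor/ceil bin edges.
* **Degenerate Grad-CAM maps**: a constant raw map normalises to all zeros
  rather than 0/0.

## Training protocol

The engine follows the reference protocol: Adam (moments 0.9/0.999,
eps 1e-8, no weight decay, no clipping) over exactly two parameter groups —
the backbone at 0.0002 and the texture branch plus head at 0.002 — with
cross-entropy loss, batch size 8, 25 epochs, and cosine annealing
`eta_min + (base − eta_min)(1 + cos(pi t / T_max)) / 2` with `T_max = 25`,
`eta_min = 0`, stepped once per epoch (both groups decay proportionally, so
their ratio stays 0.1). The retained checkpoint maximises validation
accuracy with ties going to the earlier epoch; the protocol source never
names a selection rule, and best-validation is the conventional choice.
Datasets are split 70/15/15 by seeded per-class shuffling with
largest-remainder rounding (ties resolved train > val > test), which keeps
every class within one item of its exact fraction in every subset.

Augmentation (training only): resize to 224, horizontal flip with
probability 0.5, rotation uniform in ±10° (bilinear, zero fill), colour
jitter with brightness/contrast/saturation factors uniform in [0.8, 1.2].
The LBP plane is recomputed from each augmented view — never cached from the
original — so the two branches always see the same geometry. Evaluation
applies the resize only.

## The backbone contract

Re-implementing EfficientNetV2-S is out of scope; the backbone is consumed
through a registry that declares a name and a pooled feature dimension.
The `"efficientnetv2_s"` entry is a feature contract (1792-d) whose
construction demands downloaded pretrained weights and therefore raises an
explicit download-required error offline — a backbone is never silently
randomly initialised when pretrained weights were requested. The bundled,
buildable stand-in `"tiny_cnn"` (4×4 average pool to 56, three conv blocks
3 → 16 → 32 → `feature_dim`, global average pool; declared dimension 32)
exercises the full training pipeline offline. Its purpose is plumbing
verification, not accuracy: results with it say nothing about
ImageNet-pretrained performance.

## The synthetic fixture

`generate_eye_fixture()` renders seeded 224×224 eye compositions (skin,
sclera ellipse, iris, pupil, per-image geometry jitter, Gaussian pixel noise
sd 3) in five classes chosen so that colour and texture jointly — but
neither alone — separate all classes:

* *normal*: clean composition;
* *cataract*: central Gaussian haze over the lens (whitening with a smooth
  gradient);
* *conjunctivitis*: sclera redness (+75 red, slightly depressed green/blue);
* *uveitis*: the **same** redness, plus granular speckle — 3×3-smoothed
  Gaussian noise (sd 45 before smoothing) on the sclera;
* *eyelid*: a dark occluding band with a wavy edge over the top third.

The uveitis speckle is spatially smoothed on purpose: iid per-pixel speckle
is invisible to LBP, which only records difference signs, so an unsmoothed
speckle would leave uveitis and conjunctivitis texture-identical and reduce
the fixture to a colour problem. Smoothing correlates neighbouring pixels
and shifts the code histogram measurably (`texture_separability()` reports
the chi-square distances). What the fixture does **not** emulate: real
acquisition optics, JPEG artefacts, anatomical variability, class
imbalance, or the actual image statistics of any clinical dataset — passing
the end-to-end tests demonstrates that the pipeline can learn jointly
colour- and texture-coded classes, not clinical performance.

Default conditions for the end-to-end checks: 40 images/class, batch 8, the
full 25-epoch protocol for the `full` and `no_se` variants (seeds 1–3 and
seed 1 respectively), and a 10-epoch budget for the `lbp_only`
chance-accuracy check — the shorter budget makes that check harder, not
easier, and keeps the suite at desk scale. With these conditions the full
variant reaches ≥ 0.95 final training accuracy and ≥ 0.80 test accuracy in
the median over the three seeds; the tests compute these quantities fresh
on every run.

## Explainability

`grad_cam()` hooks the backbone's last feature stage before global pooling
(RGB branch) and the texture branch's post-SE activations (LBP branch) —
the protocol source does not name its hook layers, and these are the last
spatially resolved stages of each branch. Channel weights are spatially
averaged gradients of the target-class logit; because the head is affine,
those gradients are exact rows of the head weight matrix propagated through
the pooling operator, no autodiff approximation involved. Maps are ReLU-ed,
bilinearly upsampled and min-max normalised.

## Implementation notes

The convolutional layers, batch norm, pooling and their backward passes are
compiled (RcppArmadillo) with single-precision GEMM via the system BLAS and
double-precision interfaces at the R boundary; forward/backward kernels are
verified against an independent double-precision R reference and against
finite differences in the test suite. Buffers persist across batches inside
an opaque cache pool, which keeps the per-batch cost allocation-free. A
fixed seed makes initialisation, splitting, shuffling and augmentation — and
therefore entire training runs — bit-reproducible on a given BLAS.

## Known limitations

* No real pretrained backbone ships with the package; plugging one in
  requires registering a backbone with loadable weights.
* Only P = 8, R = 1 LBP is implemented (multi-scale and rotation-invariant
  variants are deliberate non-goals).
* The classifier head is a single affine layer; dropout or hidden layers
  were not part of the reference description.
* Single-run metrics on small datasets carry substantial seed variance; the
  test suite uses 3-seed medians for its stochastic checks, and the same
  caution applies to any real use.
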