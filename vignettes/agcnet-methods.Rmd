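---
title: "Attention-guided cascaded vessel segmentation: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-guided cascaded vessel segmentation: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(agcnet)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter, what the
synthetic data does and does not emulate, and the places where the design
was genuinely open and a choice had to be made.

## The segmentation problem and the model

A fundus photograph is an RGB image; the target is a binary map marking
vessel pixels. Two features dominate the difficulty: vessels are a minority
class (roughly 2:8 against background), and the hardest pixels — thin
low-contrast branches, vessels crossing the over-bright optic disc — are
precisely the diagnostically informative ones.

The model is a two-stage cascade of *identical* residual U-shaped
backbones. Each backbone: one residual convolution block per resolution
level on both the encoder and decoder sides, stride-2 3×3 convolutions for
downsampling (two stages, channels 32 → 64 → 128 by default), bilinear ×2
upsampling with concatenation skip connections on the way up, and a 1×1
convolution + sigmoid head. A residual block is
conv3×3 → BN → ReLU → conv3×3 → BN, added to an identity shortcut (1×1
conv + BN when the channel count changes), with a final ReLU — the standard
composition consistent with "convolution, batch normalization, ReLU,
residual connection". The coarse stage produces a rough probability map;
the fine stage consumes the attention-gated coarse map together with the
original image and produces the refined map. Training supervises both maps
against the same ground truth (`total = main + λ·aux`, λ = 1 by default),
which keeps gradients flowing into the lower half of a deep cascade.

### The twin-backbone prior channel

The stages are described as identical twins, yet the fine stage must read
one more channel (the gated coarse map) than the coarse stage. We resolve
this by giving *both* backbones a 4-channel input: a **prior channel**
concatenated with RGB. The coarse stage has no earlier prediction, so its
prior is identically zero; the fine stage's prior is the ISAM-gated coarse
probability map. The zero prior is inert — weights reading it receive zero
gradient — and the two backbones are exact parameter twins
(`n_parameters(model$coarse) == n_parameters(model$fine)`), which the test
suite asserts.

### Inter-stage attention module

Channel-wise mean and max pooling of the input produce two H×W
descriptors. Their 2-channel concatenation passes through three *parallel,
independent* dilated 3×3 convolutions (rates 1, 2, 3; padding = rate so the
resolution is preserved; no bias, since batch normalization follows the
sum). The normalized sum goes through a sigmoid, and the resulting map in
(0,1) multiplies every channel of the input. Consequences the tests pin
down: gating can only attenuate (|out| ≤ |in| elementwise), and a
single-pixel perturbation can influence the attention map only within
Chebyshev radius 3 (the rate-3 branch's 7×7 footprint).

The module's input at the cascade point is the coarse stage's *post-sigmoid
probability map*, not the logits — the intermediate output that also feeds
the auxiliary loss. The module itself is written for any channel count.

### Pixel-importance-balance loss

For each pixel, `num` counts the vessel pixels in the surrounding
(2r+1)×(2r+1) box with r = 2 (a 5×5 box). The cross-entropy weight is
`−num·0.04 + 2` on vessel pixels and `num·0.04 + 1` on background pixels.
Reading the formulas: a 1-pixel-wide branch has small `num`, so its pixels
get weights near 1.96, while the interior of an 8-pixel trunk saturates
toward 1.0; a background pixel hugging a vessel is up-weighted, which
penalizes thickness over- and under-shoot. All weights lie in [1.00, 1.96],
so no pixel is silenced and none dominates.

Decisions the printed formulas leave open, and what we chose:

* **Centre pixel counts.** The double sum runs over the full box including
  the centre; we follow it literally. A vessel pixel therefore always has
  `num ≥ 1`.
* **Borders.** Box cells outside the image contribute zero — equivalent to
  zero-padding the mask, and consistent with training on zero-padded
  images.
* **Reduction.** The loss is the *mean* over pixels (and over the batch),
  not the raw sum: the sum would scale the gradient with pad size, making
  the published learning rate dataset-dependent. `reduction = "sum"` is
  available.
* **Weights are constants of the target.** They are computed from the
  ground-truth mask only, once per (augmented) sample, and receive no
  gradient. Under geometric augmentation the weights are recomputed from
  the augmented mask — they must be, since `num` is not invariant under
  rotation resampling.
* **Clamp.** Probabilities are clamped to [1e−7, 1−1e−7] before logs; the
  analytic gradient is zeroed where the clamp is active.
* Box radius, slopes and intercepts are all parameters with the published
  values as defaults, so larger pixel distances can be explored without
  code change.

## Synthetic data: what it emulates, what it does not

The generator exists so that every mechanism — loss weighting, attention,
cascade, training loop, evaluation — can be exercised and tested without
downloading fundus datasets. It emulates the *statistical structure the
method targets*, not fundus appearance:

* curvilinear vessel trees grown by seeded random walks with branching,
  stroked at widths 2–4.5 px (trunks) down to 1–2 px (thin branches);
* thin branches rendered at reduced contrast (factor 0.4) — the
  low-contrast-thin-vessel failure mode;
* one over-bright Gaussian disc placed on a trunk — the over-illuminated
  optic disc failure mode;
* a textured warm-toned background, additive Gaussian noise (sd 0.05), and
  an inscribed-circle field-of-view mask mirroring camera geometry;
* class imbalance: a stamping budget caps vessel coverage at 24% of the
  image, so the background:vessel ratio is always at least 3:1 (measured
  range over seeds ≈ 0.09–0.24), the regime the weighted loss addresses.

All randomness derives from one integer seed through counter-based child
seeds; the caller's RNG state is saved and restored, and identical specs
yield bit-identical samples.

What passing tests on this data *does not* show: robustness to pathology
(lesions, hemorrhages), to real optics (vignetting, chromatic blur), to
annotation noise, or to the scale of real images. Results at 64×64 with a
narrow network are directional evidence about the mechanisms, not about
benchmark performance.

## Training and evaluation conventions

* **Recipe defaults** follow the published setup: Adam, lr 1e−3, batch 2,
  200 epochs, ×0.1 decay at epochs 150 and 190, λ = 1.
* **Augmentation** is online (drawn fresh each epoch): random horizontal
  and vertical flips, rotation uniform in ±180°, and colour jitter
  (brightness/contrast/saturation factors 0.2). Magnitudes are not stated
  in the source recipe; these defaults are configurable and logged in the
  config object. Geometric transforms apply to image and mask identically,
  with nearest-neighbour resampling for the mask so it stays binary.
* **Padding** is centred zero-padding to the smallest square multiple of
  16 covering the image (584×565 → 592×592, 999×960 → 1008×1008), inverted
  exactly by cropping at evaluation time. The remainder pixel goes to the
  bottom/right; the offsets are recorded in the pad spec, so the round trip
  is bit-exact.
* **Best epoch.** The returned model is the epoch with the highest
  test-set AUC, mirroring the published best-epoch protocol. This is an
  optimistic protocol (the test set influences model selection); we keep
  it for fidelity and provide `select_by = "last"` as the conservative
  alternative.
* **Metrics** pool pixel counts over the whole test set before forming
  SE/SP/ACC/F1 (one dataset-level number); per-image values are also
  reported. The FOV mask, when present, restricts all counts; this is
  configurable because published practice is ambiguous. Degenerate
  single-class regions yield NaN with a warning rather than a silent 0.
  AUC uses the rank (Mann–Whitney) formula with average ranks for ties.
* **Batch normalization** uses batch statistics in training and running
  averages (momentum 0.1, eps 1e−5) in evaluation. Stride-2 downsampling
  convolutions carry BN + ReLU like every other convolution in the
  backbone; skip connections tap the last same-resolution block output.
  Both points are unstated in the source description; we chose the
  standard reading and made the block internals explicit in code.
* **Initialization** is Kaiming-style normal for convolution kernels,
  unit/zero for BN, drawn deterministically from the config seed; no
  pre-trained weights anywhere.

## Desk-scale study conditions

The heavy end-to-end checks run at sizes chosen once as a faithful
miniature: 64×64 synthetic images, 20 training / 8 test samples (the
train/test cardinalities of the real datasets), a base-8 network
(schedule 8/16/32 — same shape, quarter width), 30 epochs with decay at
22/27 for the learning check, and a 3-seed, 12-epoch, identical-budget
comparison for the directional claim that the full configuration (cascade
+ aux supervision + attention + weighted loss) matches or beats the
single-backbone plain-CE baseline in mean test AUC. On this data the full
model reaches AUC ≈ 0.99 within those budgets.

## Numerical and degenerate-input behaviour

* Image sizes must be divisible by 4 (two stride-2 stages); violations
  raise an error naming the requirement rather than silently resizing.
* `n_trees = 0` yields a legitimate background-only sample; metrics on
  single-class regions return NaN with a warning; ROC requires both
  classes and says so.
* Bilinear ×2 upsampling uses half-pixel-centre alignment with edge
  clamping; its backward pass is the exact transpose (verified by finite
  differences).
* Channel max-pooling routes gradient to the first arg-max on ties.
* All forward/backward passes are deterministic on CPU for a fixed seed;
  training twice with one seed gives identical loss curves.

## Known limitations

* CPU only, plain R/C++ double precision; no GPU, no mixed precision, no
  multi-threading beyond BLAS. Full-resolution 200-epoch training is
  therefore far slower than a framework implementation — the package's
  purpose is a complete, testable, dependency-light implementation of the
  method, not benchmark-scale throughput.
* The cascade is fixed at two stages; deeper iterative refinement is out
  of scope.
* Channel attention (as opposed to spatial) is deliberately absent.
* The CHASE ground-truth annotator is ambiguous in published practice; we
  default to the first annotator, configurable.
* GIF rasters (the format of some legacy annotation files) need the
  optional EBImage reader; PNG and TIFF are supported natively.
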