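---
title: "Model and methods behind pneunet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind pneunet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pneunet)
```

## The problem and the model

pneunet implements a compact convolutional network for binary pneumonia
detection on frontal chest radiographs, built from four ideas that each
target a property of this imaging task:

* **Depthwise-separable feature fusion.** A 3x3 stem convolution (32
  channels) feeds three sequential depthwise-separable blocks (depthwise
  3x3 + batch norm + ReLU, pointwise 1x1 + batch norm + ReLU, dropout).
  The stem output and the three block outputs are concatenated into a
  128-channel tensor, so the later stages see features at four depths at
  once. A standard convolution costs `k^2 * C_in * C_out`
  multiply-accumulates per position; the separable factorization costs
  `k^2 * C_in + C_in * C_out`, a ratio of `1/C_out + 1/k^2` (about 0.14
  for a 3x3, 128-to-32 layer). `complexity_report()` tabulates both per
  layer.
* **Squeeze-and-excitation channel attention.** Each channel is pooled to
  its spatial mean (`se_squeeze()`), passed through a dense bottleneck of 8
  units with a rectifier, expanded back to 128 channels, and squashed by a
  sigmoid; the resulting gates in (0, 1) rescale the channels. Radiograph
  channels are not equally informative, and the gate lets the network
  emphasize the ones that are.
* **Atrous spatial pyramid pooling.** After a stride-2 depthwise
  downsample, four parallel branches — a 1x1 convolution and three 3x3
  dilated convolutions at rates 1, 3 and 6, each to 32 channels — are
  concatenated and fused by a 1x1 convolution back to 128 channels.
  Dilation widens the receptive field without extra parameters, so
  opacities of different sizes are seen at matched scales. All branches
  are same-padded: spatial dimensions never change inside the module.
* **Learnable pooling.** Instead of global average pooling, a two-stage
  1x1-convolution head (128 to 128, then 128 to 1) plus a sigmoid produces
  a spatial attention map `A` in (0, 1), and the feature vector is the
  unnormalized weighted sum `F_pooled[c] = sum_ij F[i,j,c] * A[i,j]`.
  The sum (rather than a normalized mean) follows the defining formula;
  `learnable_pool(..., normalize = TRUE)` exposes the normalized variant,
  off by default. Global average pooling remains available as an ablation
  (`pooling_mode = "gap"`), with no trainable parameters.

A dropout layer and a dense sigmoid unit close the network. The positive
class is pneumonia throughout.

The two-stage pooling head deserves a note: a single 1x1 convolution to one
channel has 129 parameters, while the architecture's printed audit carries
16,641 for this stage. The only head consistent with both is the two-stage
composition 128->128 (16,512) followed by 128->1 (129), which subsumes the
single convolution as its second stage; that is what `build_pneunet()`
constructs and `param_report()` audits.

## Parameter audit

`param_report()` counts trainable parameters from the live weight arrays of
the assembled graph; `count_parameters()` provides the same arithmetic
declaratively. The audited counts for the default configuration are

| layer | parameters |
|---|---|
| stem 3x3 conv, 3->32 | 896 |
| squeeze-and-excitation (128, bottleneck 8) | 2,184 |
| stride-2 depthwise 3x3, 128 ch | 1,280 |
| pyramid 1x1 branch, 128->32 | 4,128 |
| each dilated 3x3 branch, 128->32 | 36,896 |
| pyramid fuse 1x1, 128->128 | 16,512 |
| learnable pooling head | 16,641 |
| classifier dense 128->1 | 129 |

plus batch-norm scales/offsets (2 per channel) and the depthwise-separable
blocks. Input images are declared 224x224x3; grayscale radiographs are
replicated across the three planes so the 896-parameter stem applies
unchanged.

## The numeric engine

No deep-learning framework is used: batched activations are `(H, W, N, C)`
arrays, and every convolution is evaluated as one BLAS matrix product per
kernel tap (column-major reshaping makes the `(H*W*N) x C` view free).
Reverse-mode gradients are hand-derived per layer and verified in the test
suite against finite differences and brute-force convolution oracles.
Same-padding uses the `ceiling(n/stride)` output convention, with the extra
pixel trailing for even sizes under stride 2. Batch normalization is
channel-wise over the spatial and batch axes (momentum 0.9, epsilon 1e-5);
dropout is inverted, so evaluation mode is the identity.

Initialization: variance-scaling (fan-in) normal kernels, zero biases, unit
batch-norm scales, all from a single seed (two builds from one seed are
bit-identical). Two deliberate exceptions:

* the classifier dense layer starts at zero, so the output opens at
  probability 0.5 regardless of the scale of the pooled features — the
  attention pooling is an unnormalized sum, so its outputs are of order
  `H'W'` and a generic init would saturate the sigmoid;
* the attention head's output bias starts at `sigmoid^-1(1/(H'W'))` (with
  0.1-scaled kernels), so the initial attention map integrates to roughly
  one and the pooled sum opens at the scale of the global average it
  replaces. Training is free to grow the map from there. The pooling
  formula itself is untouched by both choices.

## Training recipe

`train_config()` defaults to the standard recipe: Adam (beta1 0.9, beta2
0.999), fixed learning rate 0.001, batch size 32, up to 50 epochs, binary
cross-entropy (probabilities clamped at 1e-7) plus an L2 penalty of
lambda = 0.001 on convolution and dense kernels — not biases and not
batch-norm parameters — dropout 0.3 after each separable block and before
the classifier, and early stopping with patience 7. "Improvement" is a
strict decrease of validation loss (min-delta 0, earliest minimum wins
ties); the counter runs from the last improvement, so a stop at epoch
`best + patience` is the expected signature. A checkpoint is captured at
every new validation-loss minimum and the best one is returned; reloading
it reproduces the recorded best validation loss. Validation loss is plain
cross-entropy without the L2 term, so model selection tracks fit, not
kernel norms.

**Batch-norm inference statistics.** Exponential moving averages (momentum
0.9) are kept as in-epoch bookkeeping, but before each validation pass the
running statistics are re-estimated exactly — pooled moments from forward
passes over the training set with the current weights and dropout off
(precise batch norm, `refresh_bn_stats()`). In a short-run regime of a few
optimizer steps per epoch the moving averages are both noisy and biased by
dropout-mode activations, and the unnormalized attention sum would amplify
that shift directly into the classifier logit; re-estimation makes the
evaluated model consistent with the weights being evaluated. Checkpoints
store the re-estimated statistics.

Determinism: shuffling and dropout masks derive from the training seed;
identical configurations give identical histories in this single-threaded
engine.

## Synthetic radiographs

`generate_synthetic()` builds seed-deterministic phantoms: a bright thorax
background (gray level 200) with two darker elliptical lung fields
(darkening 90), softened edges, per-image Gaussian pixel noise (sd 8), and
— for the pneumonia class — one to three bright blobs (peak +70, Gaussian
blur sigma 6) confined to the lung fields, with the ground-truth opacity
mask retained per image. Defaults are 200 images per class at 224x224,
seed 7. Every image draws its noise from a stream keyed to its global
index, so no two records share a noise field; with zero noise and zero
opacity intensity the classes are pixel-identical by construction.

What the phantoms emulate is the *geometry* of the task: darker aerated
lungs on a brighter thorax, class-defining opacities inside the lung
fields, pixel noise. What they deliberately do not emulate: anatomical
variability between patients, ribs and mediastinal structure, acquisition
artifacts, and label noise. A model and test suite passing on phantoms
therefore demonstrates that the pipeline learns and localizes the intended
class signal — not that it reaches any particular accuracy on real chest
radiographs; full-scale runs on the public pneumonia dataset use the same
code paths via `load_directory()`.

## Desk-scale study conditions

The end-to-end checks train on the default 400 phantoms, split 80-10-10
(stratified, largest-remainder allocation; explicit-counts mode reproduces
printed sizes such as 4,646/586/624 verbatim), preprocessed to 24x24
pixels, for at most 10 epochs on one CPU. The 24-px resolution is the
package's desk-scale choice: it preserves the class signal after
anti-aliased downscaling while keeping a full training run in the minutes
range. Preprocessing is grayscale conversion (Rec. 601 luminance), bilinear
resize — with a Gaussian anti-aliasing prefilter (sigma = 0.5 * scale) when
downscaling, without which decimation aliases away structures smaller than
the sampling stride — intensity scaling to [0, 1], and replication to three
channels.

## Evaluation statistics

`confusion()` thresholds scores at 0.5 (configurable) with pneumonia
positive: TP = pneumonia called pneumonia, FN = pneumonia called normal,
FP = normal called pneumonia, TN = normal called normal. (Published prose
around such counts sometimes swaps the FP/FN glosses; the counts are the
authoritative definition here, and the package's convention reproduces
every derived score.) `report()` gives per-class precision/recall/F1 with
support, accuracy, macro and support-weighted averages; zero-denominator
scores are defined as 0 and flagged. Display rounding is half-up to two
decimals. `roc_auc()` sweeps tie-grouped thresholds and integrates by
trapezoid — equal, to numerical precision, to the Mann-Whitney
pair-counting estimator with ties at one half. `mcnemar()` implements the
paired chi-squared test on discordant counts, continuity-corrected by
default (numerator floored at zero), with the one-degree chi-squared upper
tail.

## Grad-CAM

`grad_cam()` targets a spatial stage (default: the pyramid fuse output, the
final convolutional stage), weights each activation channel by the spatial
mean of the gradient of the output *probability*, rectifies the weighted
sum, min-max normalizes, and bilinearly upsamples to input resolution.
Rectify-then-normalize is the conventional order; maps that are identically
zero before normalization (for example under a frozen zero classifier) are
returned as all-zero and flagged rather than divided by zero. Saliency is
computed for the pneumonia direction of the single sigmoid output; a
negative-class map is not defined. `gradcam_localization()` scores maps
against the generator's ground-truth opacity masks (mean value inside vs
outside), which is how the pipeline's interpretability is validated
offline.

## Numerical and design notes

* Early stopping uses strict improvement; a worked trace whose minimum sits
  seven epochs before the halt stops exactly at `best + 7`.
* The split allocator works per class with largest remainders, train first,
  then validation from the remainder (scaled to the global proportions),
  test taking what is left; per-class deviation from exact proportionality
  stays below one item per split.
* The 1-D dilated convolution `atrous_conv_1d()` is valid-mode and errors
  when the kernel span exceeds the signal; it is the oracle against which
  the 2-D dilated branches are tested (dense convolution with zero-inserted
  kernels is the second, independent oracle).
* Checkpoints serialize the architecture, all weight arrays, batch-norm
  running statistics and the best-epoch bookkeeping; a JSON sidecar carries
  the architecture as structured text. Round trips are bit-identical.
* The architecture table's printed total (~1.84 M) is not reproducible from
  its own rows (~0.17 M); the per-layer counts are authoritative and the
  total is reported as their sum.

## Known limitations

* The engine is CPU-bound R; full-resolution (224 px) training is supported
  but slow — the design target is correctness, auditability and desk-scale
  reproducibility, not throughput.
* Phantom results do not transfer to clinical performance claims (see
  above).
* McNemar comparisons against external baselines require their prediction
  files; the package computes the test but ships no baseline models.
* DICOM ingestion and augmentation are out of scope; inputs are PNG/JPEG
  trees in the class-per-folder convention.
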