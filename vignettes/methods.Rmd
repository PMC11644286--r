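---
title: "A parallel CNN-transformer network for polyp segmentation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A parallel CNN-transformer network for polyp segmentation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Colorectal polyps are lesions of the colonic mucosa whose early detection in
colonoscopy frames substantially reduces cancer risk; clinical miss rates are
high because polyps vary widely in size, color and texture and their
boundaries blend into the surrounding mucosa. Pixel-wise segmentation — a
binary mask per frame — is the first automated step. Convolutional encoders
capture local texture well but have no mechanism for global context; vision
transformers model global relations between image regions but are weaker on
local boundary evidence. This package implements a hybrid of the two: both
encoders run in parallel on the same frame and their feature pyramids are
fused by a channel-attention module before an attention-gated decoder
restores full resolution.

## Architecture

**Input.** Batches of RGB images `(H, W, 3, N)` with `H`, `W` divisible by
16 (the published protocol resizes frames to 256x192; masks are resized
nearest-neighbour so labels never bleed).

**Transformer branch.** The image is cut into `P = 16` pixel patches,
`N = HW/P^2` per image; each flattened patch is linearly projected to the
embedding dimension and a learned position code is added. A stack of
pre-norm transformer blocks follows — layer normalization, multi-head
self-attention `softmax(q k^T / sqrt(D_h)) v` per head, and a GELU MLP, each
wrapped in a residual connection. Tokens are then reshaped back to the
`H/16 x W/16` grid and two bilinear-upsample + conv + batch-norm stages
produce the pyramid `t0, t1, t2` at scales 1/16, 1/8, 1/4.

**CNN branch.** A residual convolutional encoder in the ResNet-34 layout
(stride-2 stem; three stages of basic blocks, the first block of each stage
downsampling with a projection shortcut) reaches 1/16 scale, followed by the
same two upsample stages — optionally fused with the encoder's skip
features — to emit `r0, r1, r2` with shapes identical to the transformer
pyramid.

**Fusion ("Mugen") module, one per level.** The transformer features pass
through a squeeze-and-excitation gate: global average squeeze to one value
per channel, a two-layer bottleneck `C -> C/r -> C`, and sigmoid gates that
rescale each channel. The CNN features pass through the max-pool variant of
the CBAM channel gate: the squeeze is a global *max* only — average pooling
is deliberately removed so the gate reacts to the strongest local (edge)
activation rather than the average response. The two attended maps are
concatenated and projected by a 3x3 conv + batch-norm + ReLU, and a 1x1
projection of the *raw* concatenation is added back as a residual: zeroing
the learned projection leaves exactly the skip path, which keeps gradients
healthy early in training. The bottlenecks use a leaky activation
(slope 0.01) so a channel gate cannot die at initialization in the narrow
width-reduced configurations.

**Decoder.** `z1 = upconv(y1)` at 1/8; an additive attention gate computes
per-pixel coefficients `alpha = sigmoid(psi(relu(W_g z + W_x y)))` from the
coarse gating map and the next fused map, suppressing irrelevant regions
before each upsampling step; `z2 = upconv(AG(z1, y2))` at 1/4,
`z3 = upconv(AG(z2, y3))` at 1/2, and a 1x1 sigmoid head at full
resolution yields `zout`. All upsampling is bilinear x2 followed by a 3x3
conv — deterministic and free of checkerboard artifacts; transposed
convolutions are not used.

**Deep supervision.** Besides `S_z = zout`, two side maps are supervised:
`S_t` (1-channel head on the finest transformer map) and `S_r` (same on the
CNN map), both upsampled to full resolution through the same bilinear
pipeline.

## Loss

Each supervised output is scored against the mask `G` with

* a boundary weight map `w = 1 + gain * |mean_k(G) - G|` (window `k = 31`,
  gain 5). The window mean is taken over in-image pixels only, so `w == 1`
  wherever the mask is locally constant — including at the image border —
  and rises toward `1 + gain` next to mask boundaries;
* the weighted soft IoU loss `1 - sum(w p G) / sum(w (p + G - p G))`, a
  global overlap constraint;
* the weighted binary cross-entropy normalized by `sum(w)` (so a constant
  weight map reproduces plain BCE exactly), a pixel-level constraint.

They combine as `L = L_IoUw + n * L_BCEw` with `n = 6/5`, weighting the
pixel-level term slightly higher because polyp edges are faint. The total
loss sums the three outputs, `alpha L(G, S_t) + beta L(G, S_r) +
gamma L(G, S_z)`; the per-output weights are exposed in `loss_config()` and
default to 1 each, since nothing in the protocol suggests an asymmetry.
Training computes this loss on the pre-sigmoid logits through the package's
own reverse-mode autodiff tape, with predictions eps-clamped (`1e-8`) before
logarithms.

## Evaluation metrics

Six scores per image, averaged over a dataset (`metric_config()` holds the
constants):

* **mDice, mIoU** — set overlaps of the prediction binarized at 0.5.
* **MAE** — mean absolute error of the *continuous* sigmoid map.
* **Weighted F-measure** `(1+beta^2) P R / (beta^2 P + R)` with
  `beta = 1/2` and precision/recall from soft confusion counts
  (`tp = sum(D G)` etc.). The pixel-weight exponent is fixed at 1, under
  which the weighted precision/recall reduce to the plain ones; the full
  location-dependent weighting is deliberately not implemented.
* **S-measure** — `alpha S0 + (1-alpha) Sr` with `alpha = 0.5`. The
  object-aware term mixes foreground and background scores
  `2 xbar / (xbar^2 + 1 + 2 lambda sd(x))` (`mu = 0.5`, `lambda = 1`); the
  region-aware term cuts both maps into four quadrants at the ground-truth
  centroid and averages an SSIM-style similarity with weights proportional
  to quadrant pixel area, following the metric's published reference
  algorithm (sample standard deviations, centroid rounded to the grid,
  empty quadrants scoring 1 with zero weight). Degenerate ground truths
  fall back to `1 - mean(pred)` (all background) or `mean(pred)` (all
  foreground).
* **E-measure** — both maps are centered by their global means and the
  pixelwise alignment `2 phi_G phi_D / (phi_G^2 + phi_D^2)` is averaged.
  This is implemented literally as stated, *without* the quadratic
  enhancement function of the measure's original formulation; the score is
  clamped to [0,1] for reporting, and two constant maps compare as 1 when
  equal and 0 otherwise.

Every denominator carries an eps floor of `1e-8` and bounded metrics are
clamped to [0,1] after computation.

## Synthetic scenes

`generate_sample()` draws bright, reddish, deformed-elliptical blobs on a
smoothly mottled background: base radius uniform in `radius_range`
(default 6-16 px on a 64x64 canvas), a four-harmonic Fourier perturbation
of the radius (amplitude up to 12%), axis ratios in [0.85, 1.18], boundary
blur (Gaussian sd 1.5 px) applied to the image only, foreground/background
contrast 0.35, additive noise sd 0.03. These defaults emulate
small-to-medium polyps with unclear boundaries: the mean foreground
fraction over many scenes sits in the 2-30% band. Every sample derives its
own random stream from `(base_seed, index)`, so generation is
order-independent and bit-reproducible; `generate_dataset()` writes PNG
pairs plus a manifest with a seeded 7:2:1 train/val/test split.

What the generator does **not** emulate: specular highlights, instruments,
motion blur, varying illumination, camera distortion, or multi-polyp
occlusion. Tests passing on these scenes therefore validate the
implementation — shapes, gradients, losses, metrics, trainability — not
clinical performance; results on real colonoscopy data require the public
polyp benchmarks and pretrained backbone weights, which are out of scope
here.

## Presets, parameters and numerical choices

| parameter | desk | paper | notes |
|---|---|---|---|
| input size (H x W) | 64 x 64 | 192 x 256 | both divisible by 16 |
| embedding / heads / depth | 64 / 4 / 4 | 768 / 12 / 12 | paper mirrors ViT-B/16 geometry |
| CNN stage widths | 16/32/64 | 64/128/256 | blocks 1/1/1 vs 3/4/6 (ResNet-34 layout) |
| pyramid channels D0/D1/D2 | 64/32/16 | 256/128/64 | decoder tail 8 vs 32 |
| SE/CA reduction r | 8 | 16 | channel dims divisible by r |
| batch / LR / epochs | 8 / 1e-3 / 20 | 16 / 1e-4 / 30 | Adam in both |

The published protocol fixes the paper preset's optimizer settings; the
desk preset is this package's own CPU-sized configuration, and its higher
learning rate (1e-3) is the standard choice for full-batch Adam on a tiny
overfitting task. The patch size is fixed at 16 (the named ViT-B/16
geometry); channel dims `D_i` are not stated in the protocol and default as
above. Batch-norm runs in training mode with running statistics
(momentum 0.1) used at inference; weights use He initialization, position
codes `N(0, 0.02)`.

Design points that were genuinely open, and the choices made:

* *Fusion wiring.* The residual combination of attended and raw features is
  realized as `ConvBN(concat(t_hat, r_hat)) + Conv1x1(concat(t, r))`; the
  "reduce to one channel" stack lives in the decoder head and the two side
  heads, so the decoder consumes multi-channel fused maps.
* *Decoder entry.* The first fused map (1/16) is upsampled once before the
  gate ladder so the stated ladder 1/8 -> 1/4 -> 1/2 -> full holds exactly.
  The attention gates join maps at equal scale inside the decoder; the
  exported `attention_gate()` also accepts a one-scale-coarser gating map
  and upsamples it internally.
* *CNN upsampling skips.* Whether the up-path consumes encoder skips is
  ambiguous in the source architecture diagram; it is a config flag,
  default on (U-Net practice).
* *Ablation grid.* "Backbone" is read as the CNN encoder with plain fusion
  and decoder; "+TB" adds the transformer branch with plain concatenation
  fusion; "+CB" adds the max-pool channel gate on CNN features; "complete"
  adds both attentions. This ordering makes parameter counts strictly
  monotone, which the harness asserts.
* *Empty-mask conventions.* Dice and IoU of two empty masks are 1 (logged);
  an empty ground truth with an all-zero prediction incurs zero IoU loss.

## Problem sizes used by the tests and the acceptance script

The package's own experiments are sized for a single CPU: the metric oracle
suite uses 200 random 16x16 pairs; architecture contracts run one forward
pass at 192x256 with desk widths; trainability overfits 8 synthetic 64x64
scenes for 60 full-batch Adam steps (mDice >= 0.90 is typically reached
before step 25); the generalization run trains on a 30-scene dataset at the
7:2:1 split for 25 epochs and evaluates the validation split. These sizes
are the package's choices for fast, deterministic experiments and are
stated here so they can be scaled up deliberately.

## Known limitations

* No pretrained backbone weights are shipped or downloaded; architecture
  accepts random initialization, and a checkpoint produced by
  `save_checkpoint()` can stand in where persistent weights are needed.
* The engine is plain R with BLAS matrix multiplies: fine for the desk
  preset and forward passes at the paper geometry, but full-scale training
  of the paper preset is outside its intended envelope.
* Inference uses single-scale, single-pass prediction — no test-time
  augmentation, CRF post-processing or multi-scale fusion.
* The weighted F-measure implements only the uniform pixel weighting its
  protocol fixes; the E-measure follows the stated formula without the
  enhancement variant, which can read lower than implementations that
  include it.
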