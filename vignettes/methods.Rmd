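---
title: "Methods: architecture, losses, synthetic data and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: architecture, losses, synthetic data and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific and numerical design of
**polypseg**: the segmentation model it implements, the double-loss
training objective, what the synthetic data generator does and does not
emulate, and the concrete choices made where the architecture description
leaves freedom. It states no empirical results beyond what the package's
test suite and `scripts/acceptance.R` themselves compute.

## The segmentation problem

Polyps in colonoscopy images are hard to segment because they often
differ only slightly in intensity from the surrounding mucosa, their
boundaries are optically blurred, their sizes span orders of magnitude,
and the images carry noise and illumination artifacts. The network here
addresses these with three mechanisms: a deep-supervision head that
forms a coarse lesion prior early in training, mask-gated skip fusion
that suppresses irrelevant background in the encoder features, and a
multi-kernel decoder whose parallel 3/5/7/9 receptive fields track the
size variation.

## Architecture

**Encoder.** A 7×7 stride-2 stem convolution (batch norm + ReLU), a
stride-2 max pool, then four stages of ResNet34 BasicBlocks (3/4/6/3).
Each block is two 3×3 conv–BN pairs with ReLU after the first and after
the residual sum; the shortcut is the identity when shape is preserved
and a strided 1×1 projection (with BN) otherwise. Stride-2 downsampling
happens only in the first block of stages 2–4. A literal reading of the
block equation with *every* convolution strided would collapse any
feasible input after 16 blocks, so the standard BasicBlock semantics are
used — consistent with the encoder being declared a ResNet34. Feature
taps are taken after residual blocks 3, 7, 13 and 16 (stage ends), at
strides 4/8/16/32, plus the stem tap at stride 2. The stem max pool is
required for the 5-level stride ladder {2,4,8,16,32} to close.

The default width list `[32, 64, 128, 256, 512]` follows the reference
configuration. It is incompatible with standard ResNet34 pretrained
stems (width 64); both width sets are one config field apart, and
`load_pretrained()` refuses the narrow stem explicitly rather than
guessing. Neither option is asserted to be "the" intended configuration;
the default keeps the printed widths.

**Deep-supervision head.** The stem tap and the deepest tap are each
projected by a 1×1 convolution to a common internal width (64 by
default), the deep branch is bilinearly upsampled to stem resolution,
the concatenation is refined by two 3×3 conv–BN–ReLU units, and a 1×1
convolution emits one-channel mask logits; the sigmoid of the logits is
the supervision mask. The internal width is not specified by the
architecture description; 64 keeps the head light relative to the
encoder.

**Mask-gated skip fusion.** The supervision mask probability (not the
logits — gating should be a soft [0,1] attention) is bilinearly resized
to the tap's resolution and broadcast over channels. The printed fusion
formula adds the mask itself as a residual to the gated features; as
printed the two terms live at different resolutions, so the resize is
applied to the residual term too: `X' = Conv3×3(E_j ⊙ τ(m) + τ(m))`,
the minimal correction that preserves the printed structure. An
alternative reading (`+ E_j`, a feature residual) cannot be settled from
the description and is not the default. The channel attention that
follows is the plain squeeze `σ(Avgpool(X')) ⊙ X'`, without a
bottleneck, exactly as printed; the prose variant of the block
(1×1 conv, concatenation, two 3×3 convolutions) contradicts the
equations and is not implemented.

**Multi-kernel decoder block.** Four same-padded parallel convolutions
(kernels 3/5/7/9) each produce a quarter of the output channels. Each
branch has a channel-attention submodule (global average pool →
bottleneck MLP at reduction ratio 4 → sigmoid); a spatial submodule
takes the *block input* (the formula names the input, not the trunk),
pools it over channels by mean and max, and maps the two planes through
a 7×7 convolution and a sigmoid. The output multiplies the trunk by the
sum of the two attentions, so the modulation factor is bounded in
(0, 2). The bottleneck uses a leaky rectifier (slope 0.01) rather than a
hard ReLU: the bottleneck can be as narrow as 2–4 units, and a hard ReLU
can leave every hidden unit inactive for an entire batch, silencing the
gradient path to those weights; the leak guarantees gradient flow
without materially changing the attention.

**Decoder assembly and head.** The deepest fused tap feeds the first
decoder block directly (no deeper partner exists to upsample). Each
subsequent level bilinearly upsamples ×2, concatenates the fused skip at
that scale, and applies the block. Upsampling is bilinear interpolation
throughout (the description names only "upsample"); transposed
convolutions were rejected for parameter economy and checkerboard risk.
The decoder ends at stride 4, and the head climbs to full resolution in
two ×2-upsample + 3×3-refine steps rather than one ×4 jump, again to
avoid checkerboard artifacts; a final 1×1 convolution and sigmoid emit
the probability map. The sigmoid lives inside the network, and the BCE
loss consumes probabilities.

**Interpolation convention.** All resizes use bilinear interpolation
with the half-pixel-centre (corner-aligned-off) convention. One global
convention avoids half-pixel disagreements between the supervision head,
the skip gates and the decoder.

## The double loss

With prediction `p`, binary label `q`, and N pixels:

* `BCE(p,q) = −mean(q log p + (1−q) log(1−p))`, with `p` clamped to
  `[clip, 1−clip]`, `clip = 1e-7`, so the loss is finite at saturated
  predictions.
* The soft Dice coefficient `(2Σpq + ε)/(Σp² + Σq² + ε)` with
  `ε = 1e-6` added to numerator and denominator; ε guards batches whose
  masks are empty. Inside every loss, "Dice" means one minus this
  coefficient — the only reading under which minimisation improves
  overlap.
* `BCE_Dice = α·BCE + (1−α)·DiceLoss` with α = 0.5.
* `L_global = BCE_Dice + DiceLoss`. As printed this carries an extra
  Dice term, making the effective weights 0.5/1.5 rather than 0.5/0.5;
  it is implemented as printed.
* `L_local = DiceLoss(m↑, q)`: the supervision mask is bilinearly
  upsampled to label resolution and compared against the
  *full-resolution* ground truth. Downsampling the ground truth instead
  would require committing to a mask-decimation rule that is nowhere
  specified.
* `L_total = L_global + λ·L_local` with λ = 1 (the two losses are never
  weighted against each other in the protocol; λ is exposed for
  ablation, and λ = 0 reproduces the "no local loss" variant).

## Training protocol

Batch size 4, Adam with β₁ = 0.9 (the protocol lists "momentum = 0.9"
alongside Adam, which has no classical momentum knob; it is read as the
first-moment decay), β₂ = 0.999, and a learning rate annealed from 1e-4
to 1e-5. The schedule connecting the two endpoints is not specified;
cosine annealing is used because it is smooth and endpoint-exact (epoch
0 gives exactly 1e-4, the final epoch exactly 1e-5, the midpoint
(1e-4+1e-5)/2). No weight decay and no data augmentation are applied
(none are described). Validation, when a validation directory is
configured, runs after every epoch and selects the best checkpoint by
mean per-image DSC; the package never makes a train/validation split
itself because no split rule is specified — the CLI takes explicit
directories.

Convolution weights are He-normal initialised, biases zero, batch-norm
scale 1 / shift 0. Batch normalisation uses batch statistics (and
updates running estimates, momentum 0.1) in training mode and running
estimates in inference mode. A non-finite loss aborts training with the
component breakdown rather than continuing silently.

## Evaluation conventions

Probability maps are binarised at `p ≥ 0.5` (the threshold is a
parameter; the ≥ convention is asserted by tests at the boundary).
Dataset-level aggregation defaults to the mean of per-image metrics —
the dominant convention for the public polyp benchmarks — with pooled
pixel counts available via a flag. A 0/0 metric is defined as 1 when
both the reference and the prediction are empty (a correctly predicted
empty image) and 0 otherwise; this matters for synthetic samples with
zero lesions. Precision–recall sweeps pool confusion counts over the
dataset at each threshold.

## The synthetic data generator

The generator emulates the statistical challenges the architecture
targets, on a 3-channel background of smoothed Gaussian texture
(base intensity 0.45, texture sd 0.05):

* **size variation** — each lesion's area fraction is drawn uniformly
  from `lesion_area_fraction_range` (default 0.02–0.3 of the image, 1–3
  lesions), giving foreground fractions that span more than an order of
  magnitude across a dataset;
* **organic shapes** — a rotated ellipse (aspect ratio 0.6–1.8) whose
  boundary radius is perturbed by a random trigonometric series of 2–5
  harmonics with total amplitude ≤ 20 % of the radius;
* **low contrast** — the lesion raises intensity by `contrast_delta`
  (default 0.15 on the [0,1] scale);
* **blurred boundaries** — the silhouette is Gaussian-blurred
  (`boundary_blur_sigma`, default 2 px) before compositing, while the
  mask remains the sharp, unblurred silhouette union;
* **noise** — per-pixel Gaussian noise (`noise_sigma`, default 0.03).

Because the free composite of a random texture and a blurred silhouette
would make the realised inside/outside contrast a random variable
dominated by texture fluctuations, the generator *calibrates* it: after
compositing and before noise, a uniform offset inside the mask sets the
inside-minus-outside mean difference exactly to `contrast_delta`. The
nominal contrast is therefore a property of every sample (up to pixel
noise), which is what the contrast property test verifies at its
standard error. Defaults were chosen once as a plausible desk-scale
stand-in for low-contrast endoscopy; no quantitative lesion-size
distribution is available to anchor them.

Every sample is a pure function of `(spec, seed, index)`: the per-sample
RNG stream is a counter-based mix of seed and index, and the session RNG
is saved and restored around generation, so datasets are
order-independent and byte-identical on regeneration. Masks are stored
as 8-bit {0, 255} PNGs and thresholded at 127/255 on read; images
round-trip up to 8-bit quantisation (1/255).

What the generator does **not** emulate: specular highlights,
instruments, vignetting, perspective or non-uniform illumination, and
texture *inside* the lesion. Tests passing on this data therefore
demonstrate that the architecture, losses, gradients and training loop
are correct and that the network can learn low-contrast blob
segmentation — not that it reaches any particular accuracy on clinical
endoscopy data, which requires the real benchmarks and GPU-scale
training.

## Problem sizes

The test suite and the acceptance script run everything at desk scale,
chosen as the package's own verification sizes: unit tests use a reduced
architecture (widths 8–16) at 64 px; the shape-contract and
gradient-flow checks run the full reference widths at 64–256 px; the
learning check trains the full 33.5 M-parameter network on 8 synthetic
64 px samples for 200 optimisation steps at the published optimiser
settings and requires training-set mean DSC ≥ 0.95. These sizes exercise
every code path end to end on a single CPU core.

## Known limitations

* The engine is double precision and single threaded; it is sized for
  desk-scale verification and small studies, not for full benchmark
  training (no GPU path, no mixed precision, no multi-device support).
* Batch normalisation couples samples within a batch in training mode;
  inference is strictly per-sample (verified by the batch-independence
  test in inference mode).
* JPEG input requires the optional EBImage package; PNG is native.
* The pretrained-import path expects a ResNet34 state dict as a named R
  list (or RDS); it never downloads weights and is not exercised by
  default configurations because of the stem-width mismatch noted above.
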