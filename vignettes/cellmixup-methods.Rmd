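---
title: "Oversampling imbalanced cell images: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oversampling imbalanced cell images: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the science it implements: the
augmentation models and their assumptions, the parameters that matter, what
the synthetic fixture does and does not emulate, and the choices made where
the design was genuinely open.

## The problem

Single-cell image collections are long-tailed: a handful of morphological
classes dominate, and the biologically critical classes — mitotic phases of
nucleated blood cells, storage lesions of red cells — may have only a few
tens of labelled examples. Cross-entropy training on such data yields a
classifier that is accurate overall yet nearly blind on the rare classes,
which is why accuracy is the wrong summary and the package reports macro F1
(the unweighted mean of per-class F1) alongside it.

`cellmixup` attacks the problem at the data level, with three synthetic-image
routes of deliberately different character, and at the sampling level, by
controlling how those images enter each mini-batch.

## Images and intensity scale

Every image is a plain `H × W × 3` array on the canonical [0, 255] scale;
8-bit files map one-to-one. The rotation geometry of nonlinear mixup (radii,
circles in the colour cube) is defined on raw pixel intensities, so no
normalisation is applied before augmentation; networks normalise internally
([0, 1] for the classifier, [−1, 1] for the GAN). Grayscale inputs are
promoted by channel replication (`I_R = I_G = I_B`). Dataset loading is
lexicographic in class and file names so seeded runs are reproducible.

## mixup

A synthetic sample is `y = λ I₁ + (1 − λ) I₂` with both references drawn,
without replacement, from the combined pool (originals plus WGAN-generated
images) of a *single* class; the blend keeps that class's label and no label
mixing occurs. λ is uniform on [0.15, 0.85] — the truncation keeps the blend
visibly different from both parents — and is redrawn for every generated
sample. Outputs stay inside the per-pixel convex hull of the inputs, so no
clipping is ever needed. Whether a pair may consist of two generated images
is not constrained: the pool is treated as one set.

The double-interpolation variant (`bilinear_mixup()`, mixup applied to two
first-stage mixup images) is exposed for comparison but unused by the
default pipeline: interpolating twice drifts the result away from the
original pixel distribution, which in practice weakens rather than
strengthens the regularisation, though it can serve when out-of-distribution
sampling is wanted.

## Nonlinear mixup

The mixup image is then rotated in RGB colour space: each pixel
`(I_R, I_G, I_B)` is a point in the colour cube, and one `(axis, θ)` pair —
axis uniform over {R, G, B}, θ uniform over [0°, 360°), redrawn per generated
image — rotates *all* pixels about that colour axis (row-vector times
rotation matrix). The component along the rotation axis is untouched and
the Euclidean norm of every pixel vector is preserved, so e.g. a B-axis
rotation moves a pixel on the circle of radius `sqrt(I_R² + I_G²)` centred at
`(0, 0, I_B)`. The spatial layout is untouched; only colour appearance
changes.

Two under-specified corners were resolved as follows:

* **Out-of-cube values.** A rotation can leave the [0, 255] cube (a saturated
  red pixel rotated 90° about B lands at (0, −255, 0)). The package clips
  back to the cube — the least surprising choice, preserving a valid image —
  and exposes `clip = FALSE` for analysis.
* **Grayscale-derived images.** When `I_R = I_G = I_B`, rotation is still
  applied uniformly; it then introduces hue where there was none. This is
  intentional (the transform is defined pointwise, not conditionally) but
  worth knowing when augmenting promoted grayscale data.

Angles are accepted in degrees at the API and converted internally.

## WGAN-div oversampling

One generative model is trained per minority class. The critic objective is
used exactly as printed in the two source formulations, which carry opposed
sign conventions: the plain Wasserstein objective is
`E[D(x)] − E[D(x̃)]` (Lipschitz constraint via weight clipping at 0.01,
RMSprop), while the divergence objective is
`E[D(G(z))] − E[D(x)] − k·E[‖∇x̂ D(x̂)‖ᵖ]` (Adam). Both are internally
consistent min–max games — the critic ascends its objective and the
generator direction flips between the two — and the discrepancy is preserved
deliberately rather than silently harmonised. Interpolates x̂ are per-sample
uniform combinations `u·x + (1−u)·x̃`, u ~ U(0, 1).

Hyperparameter defaults: `p = 6`, `k = 2`, `n_critic = 4`, learning rate
`2e-4`, batch size 16, noise dimension 64. High intra-class-variance pools
(e.g. a prophase-like class containing a transitional sub-phase) are the
documented exception pattern: learning rate `2e-5` and `n_critic = 10`.

**Networks.** Critic and generator are compact fully-connected networks
(two hidden layers of 128 units; leaky-ReLU critic ending in an unbounded
linear score, ReLU generator ending in tanh), implemented on a small
package-internal engine with manual backpropagation. Fully-connected nets
were chosen over convolutional ones because at the package's working
resolutions (≤ 64×64, typically 24×24 in the toy experiment) they train
stably in seconds-to-minutes on one CPU, and because the divergence
penalty's parameter gradient — a double-backpropagation through the input
gradient — has an exact closed form for leaky-ReLU dense critics (the
activation's second derivative vanishes almost everywhere, so the
activation masks are constants under differentiation; the implementation is
verified against finite differences in the test suite). Hidden widths are
configurable; the training loop is architecture-agnostic up to that penalty
path.

**Enrichment.** Pools of a few tens of images are first enlarged to a few
hundred by handcrafted augmentation — random affine and mild perspective
warps (a shared projective bilinear-sampling warp), contrast scaling and
additive Gaussian noise, all clipped to range, originals kept verbatim. At
full scale the corresponding target is 800–1000 images; the toy experiment
uses 160 (see problem sizes below).

**Checkpointing.** Convergence is judged on the absolute critic loss: when
it stops decreasing (or turns upward), training has reached its useful
point. The qualitative rule is made operational as a moving average over a
20-step window with patience 5 windows and a minimum improvement of 1e-3;
the generator snapshot at the best window becomes the checkpoint used by
`generate_samples()`, which maps tanh outputs affinely to [0, 255] and
clips.

## Minority-class-focussed sampling

Each batch of `originals_per_batch` original images (drawn uniformly over
samples, so the original-data distribution during training is unchanged) is
supplemented with a synthetic-only batch: per unit of the per-class factor
`n`, exactly 2 WGAN-div + 1 mixup + 1 nonlinear-mixup images of that
minority class, keeping the total at `2^m`. The published configurations are
`8 + 4·(2+2+1+1) = 32` and `12 + 4·5 = 32`. The constraint is validated at
construction time with the exact shortfall/excess reported.

Resolved openness:

* All four synthetic images scale linearly with `n` (4 images per unit);
  the alternative reading (WGAN count fixed at 2) is rejected because the
  unit itself is defined as the `n = 1` increment.
* mixup/nonlinear-mixup images are generated lazily per batch, with fresh λ
  and θ per draw — maximum diversity at negligible cost — while WGAN images
  are drawn with replacement from a pre-generated pool.
* The final partial chunk of an epoch is padded with originals resampled
  with replacement (preserving `2^m`); a flag switches to dropping it.

The standard-sampling baseline (`standard_stream()`: synthetic images merged
into the pool, uniform draws, no supplementary batch) is provided for
comparison; its expected minority fraction equals the merged pool's.

## Synthetic fixture

The generator emulates centred single-cell crops as elliptical blobs with
class-specific radius, eccentricity, foreground intensity, a mild per-channel
tint (as from staining) and Gaussian pixel noise, at 48×48 px. The default
five-class table mirrors the regime the method targets: two majority classes
of 1000 images and three minority classes of 40, 25 and 15, with minority
morphologies deliberately close to the majority ones (radius means 9 and 17
for the majority, 11–15 for the minorities) — emulating the low inter-class
difference of consecutive mitotic phases that makes rare classes genuinely
hard. Blob centroids stay within a pixel of the image centre; intensities
stay in [0, 255]; a fixed seed reproduces the dataset bit-for-bit.

What the fixture does **not** emulate: real texture and internal structure,
focus variation, debris and segmentation artefacts, multi-channel physics.
Passing tests on the fixture therefore demonstrate that the machinery is
correct and that the sampling/augmentation strategy helps in a controlled
long-tailed setting — not that the specific F1 numbers transfer to any real
dataset.

## The toy experiment and problem sizes

`run_toy_experiment()` ties everything together at sizes chosen for minutes
on one CPU: the default fixture for training, a held-out balanced test set
of 60 images per class (a different derived seed), a working resolution of
24×24 (bilinear resize; at full scale the corresponding choice is 64×64,
by resize or centre crop depending on the source crop size), WGAN-div with
a 200-generator-step budget and 200 generated images per minority class
(enrichment target 160), and a classifier budget of 6 epochs.

The classifier is a small convolutional network — two stride-2 3×3
convolution layers (8 and 16 filters) and a dense softmax — trained with
cross-entropy, momentum SGD (momentum 0.9, weight decay 1e-4), initial
learning rate 0.02 and a step-decay schedule (×0.1 every 4 epochs). It is
intentionally modest: the sampler and augmentations are classifier-agnostic,
and a larger backbone can be substituted without touching them. The
baseline arm trains the same network on plain uniform original batches for
the *same number of optimisation steps*, so the comparison isolates the
oversampling.

With these defaults the augmented arm's minority-class mean F1 exceeds the
baseline's across seeds (the acceptance suite asserts the direction over
three seeds, not magnitudes).

## Numerical notes and limitations

* All randomness flows through R's RNG; every entry point takes or derives a
  seed, and training, generation and batch composition are bit-reproducible
  on a fixed platform.
* θ = 0 rotations are bit-identical to mixup (cos 0 and sin 0 are exact);
  rotation matrices are orthogonal with determinant 1 to 1e-9.
* Degenerate metric cases: a class never true and never predicted gets
  F1 = 0 and a flag — conservative, never inflating the macro mean.
* The gradient-penalty double-backprop is exact only for dense leaky-ReLU
  critics; swapping in another critic architecture requires extending that
  one code path.
* GAN training at desk scale produces blob-like, low-fidelity samples; they
  are diverse enough to help the sampler, but no claim is made about sample
  realism (no FID-style monitoring is included).
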