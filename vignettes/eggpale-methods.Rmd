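---
title: "Methods: flow-based abnormal lesion emphasis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flow-based abnormal lesion emphasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(eggpale)
```

This vignette is the package's own account of its model and of the design
decisions taken where the method left genuine freedom. It states no
empirical number that the test suite or `scripts/acceptance.R` does not
itself compute.

## The model

A normalizing flow is an invertible map `z = f_θ(x)` between images and
latent codes of equal dimension, composed of simple invertible layers whose
Jacobian determinants are available in closed form, so the likelihood

$$\log p_\theta(x) = \log p(z) + \sum_i \log\left|\det \frac{\partial h_i}{\partial h_{i-1}}\right|$$

is exact and can be maximized directly on a set of *normal* radiographs.
Each flow step is

* **actnorm** — per-channel affine `y = s (x + b)`, initialized from the
  first training batch so its output has zero mean and unit variance per
  channel (checked to 1e-3 in the tests);
* **invertible 1×1 convolution** — a shared `C×C` channel mixing matrix `W`
  with log-determinant `HW·log|det W|`;
* **affine coupling** — the first half of the channels passes unchanged and
  parameterizes scale and shift for the second half through a small
  convolutional network.

Between levels a *squeeze* trades spatial for channel resolution (2×2
neighborhoods to 4 channels) and a *split* factors half the channels out
into the latent code, giving the usual multi-scale layout. The latent
vector is assembled level by level (level 1 first), each block flattened in
column-major (row, column, channel) order; the layout is a recorded exact
bijection, tested by round trip.

The prior is **fixed** to the standard Gaussian rather than learned. The
enhancement geometry below measures Euclidean and chessboard distances in
latent space; an isotropic prior is what makes those distances meaningful.

### Numerical and architectural choices

The method's published description leaves several pieces open; the package
fixes them as follows and treats them as its own design choices:

* **Input scaling.** Display intensities `[0, 255]` map to
  `(x + u)/256 − 1/2` with `u ~ U(0, 1)` dequantization noise during
  training, and the deterministic bin center `u = 1/2` everywhere else, so
  enhancement is exactly reproducible.
* **Coupling networks.** Three same-padding 3×3 convolutions (widths
  `hidden_width`, ReLU in between). The last layer is zero-initialized so
  every coupling step starts as the identity. The affine scale is
  `s = exp(tanh(r))`: equal to 1 at zero weights (identity start), bounded
  in `[1/e, e]` hence away from both 0 and overflow, with the simple
  log-determinant `Σ tanh(r)`.
* **Optimizer.** Adam, learning rate 1e-4, β₁ = 0.9, β₂ = 0.999. Gradients
  are derived analytically per layer and validated against central finite
  differences (relative 1e-4) in the test suite. Any optimizer passing the
  loss-decrease smoke test would be acceptable; Adam converges fastest at
  this scale.
* **Singular-value re-projection.** At the end of every epoch each 1×1
  weight is re-projected as `U crop(Σ; 10⁻³, 10³) Vᵀ` — after the last
  optimizer step of the epoch, before evaluation. This keeps every weight
  invertible with condition number ≤ 10⁶; the operation is idempotent and
  leaves in-range matrices unchanged.
* **Desk scale.** The default configuration is 32×32 single-channel, 2
  levels × 4 steps, hidden width 64, minibatch 8, 4 epochs. Four epochs
  give three epoch-to-epoch transitions for the monotone-decrease check
  while keeping a full training run under ~2 minutes on one CPU. The
  full-scale preset (`paper512`: 512×512, 7 levels × 32 steps, minibatch 4,
  22 epochs) is shipped as configuration metadata only — it records the
  published architecture, and nothing in the package ever trains it.

## The normal hyperplane

With `N` training latents (`N` < latent dimension `d`) as the columns of
`Z`, the span of `Z` — which contains the origin — is the *normal
hyperplane* `S`. The package computes an orthonormal basis `Q` by pivoted
thin QR, dropping directions whose R-diagonal falls below
`rank_tol = 1e-10` times the largest (finite precision makes an exact-rank
assumption untenable; duplicated or near-duplicated training images reduce
the rank cleanly). Projection is `z₀ = Q Qᵀ z`, the unique Euclidean-nearest
point of `S`; `f_θ⁻¹(z₀)` is the virtually normalized image. The
factorization is done in memory — appropriate up to a few thousand training
latents at desk scale; an out-of-core or distributed factorization would be
needed at radiograph scale, and is a documented limitation. The basis
stores a hash of the generating model's parameters so a model/basis
mismatch at enhancement time is an error, not a silent wrong answer.

## Enhancement

Two schemes share the projection:

* **Euclidean**: `z* = γ z + (1 − γ) z₀` with `γ > 1`. Simple, but all
  latent coordinates move, which tends to amplify global deformation along
  with the lesion. Kept as an explicit mode for ablation.
* **Chessboard (default)**: with `Γ = γ‖z − z₀‖_∞`, each coordinate of `z`
  is cropped into `[z₀_j − Γ, z₀_j + Γ]` (the L1-nearest point of the
  hypercube around `z₀`), then `z* = β z + (1 − β) z_crop`. Coordinates
  within `Γ` of the hyperplane pass through *bit-identically* — ties at
  exactly `Γ` are treated as unchanged (closed interval), and the final
  extrapolation preserves untouched coordinates exactly, so the altered
  fraction equals the fraction with `|z_j − z₀_j| > Γ` by construction.

Defaults `γ = 0.2`, `β = 1.2` are adopted from the method's published
calibration (a grid search with subjective radiologist evaluation; no
objective criterion exists to re-derive them, so they are adopted, not
re-fit). `β > 2` triggers a warning: overly strong extrapolation causes
visible deformation. Enhanced images are clipped back to `[0, 255]` before
writing, since the inverse flow can leave the encoding range.

## Preprocessing

Raw intensities are windowed (`[center − width/2, center + width/2]` onto
`[0, 255]`, saturating outside; full-range min/max fallback with a message
when no window is available), then geometry is standardized: width scaled
to the square canvas (area averaging when shrinking, bilinear when
enlarging), height symmetrically truncated — or, a declared extension for
images shorter than the canvas, symmetrically zero-padded — and the canvas
down-sampled to model resolution by anti-aliased area averaging. Display
up-sampling uses Keys bicubic interpolation (a = −0.5), which reproduces
linear ramps exactly away from the replicated edges. Windowing precedes
resizing; both are intensity-linear, so the order affects only
interpolation rounding. The chain is fully deterministic. Readers cover
PNG and TIFF (8/16-bit); window parameters from other sources are passed
explicitly.

## Synthetic phantoms

The phantom generator emulates the gross structure of a PA chest
radiograph: a bright thorax ellipse, two darker lung ellipses, rib-like
periodic bands inside the lungs, a bright mediastinal column, per-image
geometric jitter, and Gaussian pixel noise — with ground-truth lung masks.
Nodules are radially symmetric Gaussian blobs (FWHM = diameter) with the
half-maximum disc as ROI; clinical ROIs were drawn manually, so this is a
documented divergence. Evaluation sets draw per-case nodule counts from
`{1, 2, 3}` with probabilities `(0.70, 0.27, 0.03)` — 1.33 nodules/case on
average, the density of the clinical 133-nodule/100-case evaluation set
this mirrors — and sample diameters 3–7 px and contrasts 20–40 at 32×32.

What the phantoms do **not** emulate: projection physics, scatter,
anatomical variability beyond affine jitter, overlying bones and vessels
as confounders, pathology other than blob-like nodules. Tests passing on
phantoms therefore demonstrate that the pipeline is *correct and effective
under its own assumptions* — they do not certify clinical performance,
which in the original work required human readers on validated cases.

## Evaluation

`CNR = (μ_ROI − μ_lung)/σ_lung` per nodule, before and after enhancement.
Lung statistics exclude all nodule ROIs of the case (whether to exclude is
unstated in the source method; exclusion makes the closed-form oracle
`Δ = 10/σ` for a pure-ROI perturbation exact and avoids the lesion
contaminating its own reference). Histogram bins default to width 0.1
centered at zero. The stochastic end-to-end check asserts the qualitative
analogue of the published result — more than half the nodules improve on a
50-case phantom set under fixed seeds — not the clinical 113/133 figure,
which depends on a closed dataset.

## Problem sizes and tolerances

Tests and the acceptance script train on 200 phantoms at 32×32 (4 epochs,
~1.5 min on one CPU) and evaluate 50 cases; the finite-difference Jacobian
oracle runs at 8×8 (64-dimensional Jacobian), where the full determinant is
tractable. Key tolerances: forward/inverse round trip 1e-4 (observed:
~1e-14 in double precision); log-determinant vs finite differences relative
1e-3; hyperplane contracts 1e-8; CNR vs pixel-loop oracle 1e-10.

## Known limitations

* In-memory QR limits the training-set size for the hyperplane.
* The coupling scale bound `[1/e, e]` per step limits how aggressively a
  single step can rescale; depth compensates, but very short flows are
  less expressive than an unbounded parameterization.
* No DICOM reader: window center/width must be supplied explicitly when
  images originate from DICOM.
* No lung-field segmenter is bundled; for real images the evaluation mask
  is an input.
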