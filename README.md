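# eggpale

Unsupervised emphasis of abnormal lesions in chest radiographs, built from a
generative model of *normal* anatomy.

## The problem and the approach

Faint lung nodules are easy to miss on a chest radiograph. Conventional
enhancement (contrast stretching, unsharp masking, rib suppression) alters the
whole image — normal structures included — so the reader must still compare
against the original. This package takes a different route: learn what normal
chests look like, and amplify only what deviates from that.

The machinery is an invertible *normalizing flow* `f_θ` (a Glow-style
multi-scale stack of activation-normalization, invertible 1×1 convolution and
affine-coupling steps) trained by exact maximum likelihood on normal images
only, with the latent prior fixed to the standard Gaussian `z ~ N(0, I)` so
that distances in latent space are meaningful:

```
log p_θ(x) = log p(z) + Σ_i log |det(∂h_i/∂h_{i-1})|,   z = f_θ(x)
```

The latent codes of the `N` training normals (with `N` < latent dimension)
span a linear subspace `S` — the **normal hyperplane**. For an unseen image:

1. `z = f_θ(x)`; project onto `S`: `z₀ = Q Qᵀ z` (thin-QR orthonormal basis
   `Q`). `f_θ⁻¹(z₀)` is the "virtually normalized" image.
2. Chessboard-distance interpolation: with `Γ = γ·‖z − z₀‖_∞`, crop each
   coordinate of `z` into `[z₀_j − Γ, z₀_j + Γ]`. Most coordinates pass
   through untouched; only the few that deviate strongly (those encoding the
   abnormality) are moved.
3. Final extrapolation `z* = β·z + (1−β)·z_crop` amplifies exactly those
   coordinates; `x* = f_θ⁻¹(z*)` is the enhanced image. Defaults `γ = 0.2`,
   `β = 1.2`.

Because the flow is exactly invertible, coordinates left untouched decode
back to unchanged normal structures — the enhancement is lesion-specific by
construction.

Enhancement efficacy is quantified per nodule by the contrast-to-noise ratio
`CNR = (μ_nodule − μ_lungfield) / σ_lungfield` before (`CNR₋`) and after
(`CNR₊`) enhancement, and its change `Δ_CNR = CNR₊ − CNR₋`.

Everything runs at desk scale (32×32 images, 2 levels × 4 steps) on synthetic
chest phantoms with ground-truth nodule masks; the full-scale radiograph
configuration (512×512, 7 levels × 32 steps) ships as the `"paper512"`
preset. The flow, its training loop and the analytic backward passes are
implemented in base R on BLAS matrix products.

## Worked example

```r
library(eggpale)

## train on 200 synthetic normal phantoms and build the normal hyperplane
normals <- generate_normal(phantom_spec(seed = 101), 200)
fit <- eggpale_fit(normals)
summary(fit)
#> Abnormal-lesion emphasizer fit
#>   training images: 200; latent dim: 1024; hyperplane rank: 200
#>   training loss (nats/image): -600.1 -> -949.6 -> -1151.1 -> -1280.9
#>   training-latent residual norms: [1.38e-14, 3.97e-14]

## enhance a 50-case evaluation set with injected nodules
cases <- generate_eval_set(phantom_spec(seed = 202), n_cases = 50, seed = 303)
records <- evaluate_cases(fit$flow, fit$basis, cases)
summarize_evaluation(records)
#> CNR evaluation over 68 nodules: 57 improved (83.8%)
#>   delta CNR: mean 0.099, median 0.112
```

The loss falls monotonically over the four epochs; the training latents lie
on the hyperplane to machine precision (residual norms ~1e-14), so normal
inputs are reproduced essentially unchanged, while 84% of injected nodules
gain contrast against their lung background. Single images are enhanced with
`predict(fit, img)` (or `predict(fit, img, type = "normalized")` for the
virtually normalized view), and `simulate(fit, 4)` draws synthetic normals
from the flow.

A command-line interface covering the same pipeline
(`make-phantoms`, `train`, `build-basis`, `enhance`, `evaluate`, `sample`)
ships as `inst/scripts/eggpale`.

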