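---
title: "Hybrid-domain wavelet networks for sparse-view CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid-domain wavelet networks for sparse-view CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualwave)
```

## The problem

Sparse-view CT reduces dose and acquisition time by measuring only a
fraction of the usual view angles. Filtered back-projection (FBP) applied
to angularly subsampled data produces characteristic global streaking
artifacts: the reconstruction problem becomes ill-posed and the missing
angular frequencies alias across the whole image. `dualwave` implements a
hybrid-domain learned reconstruction for parallel-beam data:

1. the sparse sinogram is linearly interpolated to the full angular grid;
2. a *radon-domain* residual CNN (RDNet) corrects the interpolation error,
   producing a completed sinogram;
3. a differentiable FBP bridge maps the completed sinogram to an image;
4. an *image-domain* residual CNN (IDNet) removes the remaining artifacts.

Both networks are multi-level wavelet CNNs (MWCNN): encoder–decoder
networks in which a stacked Haar transform replaces pooling. Because the
transform is invertible, downsampling discards nothing; the decoder inverts
it exactly and element-sum skip connections carry encoder features across.

## The wavelet algebra

The package uses the unnormalized Haar filters with entries ±1. For a 2×2
block `[[a, b], [c, d]]` (rows × columns) the four subband coefficients are

* `CA  =  a + b + c + d` (approximation),
* `CDh = -a - b + c + d` (horizontal detail, row difference),
* `CDv = -a + b - c + d` (vertical detail, column difference),
* `CDd =  a - b - c + d` (diagonal detail),

and the inverse divides by 4. No other normalization is applied, so one
level scales energy by exactly 4 (the rows of the 4×4 block matrix are
orthogonal with squared norm 4) and `iwt2(dwt2(x))` is exact to machine
precision. `wpt_decompose()` recurses on *all four* children, giving the
full wavelet-packet tree with `4^L` leaves. `dwt_stack()`/`iwt_stack()`
apply the transform channel-wise to feature maps with the frozen channel
ordering `[CA | CDh | CDv | CDd]`; the ordering is arbitrary but must stay
fixed because trained weights depend on it. The transforms are linear, so
their backward passes are closed-form adjoints (`t(M) = 4 * solve(M)`
for the block matrix `M`): `4 * iwt_stack` and `dwt_stack / 4`. No
parameters, no learned filters.

## Projection model and the differentiable bridge

`radon_forward()` computes line integrals on rays sampled at half-pixel
steps with bilinear interpolation; rotation centre `(n-1)/2` in 0-based
pixel coordinates; detector count equal to the image side, one-pixel
spacing. `radon_adjoint()` is the *exact* matrix transpose (same weights,
scatter instead of gather), which the test suite verifies with dot-product
identities to 1e-5 relative error. Angles cover the full circle
`[0°, 360°)` uniformly, matching common CT simulation practice even though
parallel-beam data is 180°-redundant.

`fbp()` filters each view in the frequency domain — the band-limited ramp
kernel (`h[0] = 1/4`, `h[n] = -1/(pi n)^2` for odd lags) with optional
Shepp–Logan or Hann apodization, zero-padded to the next power of two —
then backprojects with the adjoint and scales by `pi / n_views`. That
scaling *is* the view-spacing compensation: the same formula applies to
sparse sinograms, so intensities are comparable across subsampling
factors. Because every step is linear, the transpose of the whole map is
`fbp_adjoint()` (forward-project, then the same symmetric filtering), and
that is what backpropagation through the bridge uses. A finite-difference
check at size 16 confirms the gradient to 1e-3 relative error.

Phantom support is kept inside the inscribed circle so rays never clip
mass; per-view detector sums then conserve the image mass to 0.5%.

## Networks

`network_spec()` describes the architecture: transform depth (`levels`,
default 3), four-conv blocks, per-level channel widths, element-sum skips,
residual output. The default MWCNN realizes exactly **30 convolution
layers** — one input lift, 3×4 encoder convs, a 4-conv bottleneck, 3×4
decoder convs, one bare output conv — and the builder asserts this count.
All 3×3 convolutions use one-pixel reflective padding (the restoration
setting favours borders without ringing); convolutions followed by batch
norm carry no bias (it would be cancelled by the mean subtraction). The
final conv of every network is **zero-initialized**: an untrained residual
model is exactly the identity, and the untrained hybrid pipeline
degenerates to the linear-interpolation + FBP baseline. Training therefore
starts from a sensible reconstruction instead of noise.

Two ablation builders share the spec: `build_wcnn()` (a single-resolution
trunk behind one wavelet level) and `build_unet()` (the same multi-level
topology with max-pool downsampling and 2×2 transposed-conv upsampling).
The three builders differ only in their resampling operators, which is the
point of the comparison.

The engine behind the builders is a compact explicit-gradient CNN stack
(im2col + BLAS convolution in C++, batch norm, ReLU, Adam) written for
this package; every layer's backward pass is validated against central
finite differences in the test suite.

## Joint training

The loss is `L_total = L_radon + L_image`: the squared error of the
completed sinogram against the true full-view sinogram, plus the squared
error of the restored image against the FBP reconstruction of the true
sinogram, each as `sum((pred - target)^2) / (2N)` over a mini-batch of
`N`. The image term's gradient flows through the FBP bridge into the
sinogram network, so the two stages train in the same cycle (an optional
`domains = "image"` or `"radon"` mode trains a single stage at the same
budget for comparisons). Optimization follows the standard recipe for this
model family: Adam with `lr = 1e-4`, `beta1 = 0.9`, `beta2 = 0.999`,
mini-batch 4, learning rate ×0.9 every 20 epochs — the decay interval is
read in epochs, since a per-step decay would extinguish the rate within
the first epoch of any realistic run. Sinograms are min–max normalized by
one dataset-wide scale before entering RDNet (batch-norm stability with a
fixed physical scale); the bridge restores physical units. Measured views
are *not* re-imposed on the completed sinogram — the pipeline defines no
hard data-consistency projection — though the completed sinogram is
available for callers who want one.

One master seed drives phantom generation, parameter initialization and
shuffling; two runs with the same seed are bitwise-identical.

## Synthetic data: what it emulates and what it does not

`random_ellipses()` generates soft-edged, additively overlapping ellipses
(4×4 area-fraction supersampling; hard edges would add gridding artifacts
unrelated to angular undersampling), clipped to [0, 1], supports inside
the inscribed circle. This emulates the piecewise-smooth, high-contrast
structure of tomographic slices and yields exactly the streak artifacts
the method targets. It does **not** emulate anatomical texture, detector
noise, beam hardening, or the 512² resolution of clinical data, so
passing tests demonstrate the mechanism — sinogram completion plus
restoration beating naive inversion — not clinical performance. A real
acquisition model would also not be noiseless; the projector here is,
matching the simulation design the method was built for.

## Desk-scale study conditions

Defaults were chosen once for single-CPU reproducibility and stated here
as the package's own study conditions:

* images 64², 96 full views (divisible by the standard factors 3/4/6/12
  *and* by `2^3`, so sinograms enter the three-level networks without
  padding), subsampling factor 6 for the headline comparisons;
* training 100 phantoms, 20 epochs, channel widths `c(8, 16, 32)`;
  the full-scale widths `c(64, 128, 256)` remain the `network_spec()`
  default and are what the 30-layer architecture contract is asserted on;
* evaluation on 20 held-out phantoms; ablations at 32², 48 views,
  30 phantoms, 6 epochs, 2 seeds.

Under these conditions the classical ladder reproduces the expected
qualitative ordering (direct FBP ≪ linear interpolation + FBP < SART-TV)
and the trained hybrid model beats direct FBP by well over 2 dB while
edging out its own initialization (Linear+FBP). A briefly-trained small
network does *not* overtake a well-converged SART-TV at this scale; that
comparison flips only with full-scale training, which is outside the
package's test budget and outside what synthetic desk-scale phantoms can
demonstrate.

## Classical baselines

`sart()` is the all-view simultaneous update with ray and pixel weight
normalization and a non-negativity clamp; `sart_tv()` alternates one such
pass with 20 steepest-descent steps on isotropic TV (ε = 1e-8 smoothing),
step length 0.2 × the data-update magnitude, fixed schedule. Defaults
`relax = 1.5`, `n_outer = 100` were frozen after observing that smaller
relaxation/iteration budgets leave the data term under-converged at this
geometry, making TV smoothing erase structure rather than streaks and
collapsing the baseline toward Linear+FBP. The full adaptive
parameter schedule of ASD-POCS is deliberately not replicated; a fixed
schedule suffices for a baseline.

## Metrics

`psnr()` is `10 log10(max² / MSE)` with `max = 1` for [0, 1] images
(configurable to 255). `ssim()` evaluates the three-term
luminance–contrast–structure product with unit exponents. The printed
formula is window- and constant-free, so the community-standard protocol
is adopted: 11×11 Gaussian window (σ = 1.5), `C1 = (0.01 L)²`,
`C2 = (0.03 L)²`, `C3 = C2/2`, mean-pooled; a `"global"` single-window
mode exposes the raw formula for closed-form checks. Published SSIM values
are therefore comparable only in ordering, not bit-for-bit.

## Numerical choices and degenerate inputs

* Even dimensions are required by one wavelet level, divisibility by
  `2^L` for depth `L`; `restore()` reflect-pads and crops, the training
  loop requires divisible shapes outright.
* The ramp filter's DC term uses the band-limited kernel value 1/4,
  avoiding the DC bias of a naive `|f|` ramp on short windows.
* Zero sinograms are exact fixed points of SART/SART-TV; empty datasets,
  non-dividing factors, odd dimensions and out-of-range parameters fail
  fast with informative errors before any compute.
* SART normalization weights are clamped at `1e-6 ×` their maximum to
  avoid division by zero outside the scanned support.

## Known limitations

* Parallel-beam 2D only; no fan/cone geometries, no detector physics.
* The CNN engine is CPU-oriented and double-precision; it is sized for
  desk-scale experiments, not 512² clinical training.
* DICOM input is not supported; images enter as matrices, PNG, or RDS.
* Linear-interpolation completion assumes uniform angular subsampling
  starting at the first view, as produced by `subsample_views()`.
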