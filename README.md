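# dualwave

Sparse-view CT reconstruction with dual-domain multi-level wavelet
networks, for researchers studying learned tomographic reconstruction on
parallel-beam data.

Sparse-view acquisition (measuring only every k-th view angle) cuts dose
but makes filtered back-projection (FBP) produce global streaking
artifacts. `dualwave` implements a hybrid-domain learned pipeline:

```
sparse sinogram --(linear view interpolation)--> dense sinogram
               --(RDNet: residual completion)--> completed sinogram
               --(differentiable FBP bridge) --> artifact image
               --(IDNet: residual restoration)-> reconstruction
```

Both networks are multi-level wavelet CNNs: encoder–decoder networks in
which an unnormalized Haar transform (filters ±1, inverse /4) replaces
pooling, so downsampling is lossless and exactly invertible. Each network
predicts the *artifact residual* F(x, θ) and outputs `x − F(x, θ)`;
training minimizes the joint loss

    L_total = L_radon + L_image
            = ‖completed − y‖² / 2N  +  ‖restored − FBP(y)‖² / 2N

end-to-end: the FBP bridge is linear, its adjoint is closed-form, and the
image-domain error backpropagates into the sinogram network. The package
also ships the pieces around the model: a parallel-beam projector with
exact adjoint, FBP with Ram-Lak/Shepp-Logan/Hann filters, angular
subsampling and circular linear view interpolation, Shepp-Logan and
random-ellipse phantom generators, SART and SART-TV baselines, and
PSNR/SSIM metrics.

## Worked example: the classical ladder at 16 of 96 views

```r
library(dualwave)

ph     <- shepp_logan(64)
geom   <- ct_geometry(96)                 # 96 views over [0, 360)
sino   <- radon_forward(ph, geom)
sparse <- subsample_views(sino, 6)        # keep every 6th view
sparse
#> <ct_sinogram> 64 detectors x 16 views

rec_fbp <- fbp(sparse)
rec_lin <- fbp(interpolate_views(sparse, geom))
rec_tv  <- sart_tv(sparse)
cat(sprintf("FBP        %5.2f dB  SSIM %.3f\n", psnr(rec_fbp, ph), ssim(rec_fbp, ph)))
cat(sprintf("Linear+FBP %5.2f dB  SSIM %.3f\n", psnr(rec_lin, ph), ssim(rec_lin, ph)))
cat(sprintf("SART-TV    %5.2f dB  SSIM %.3f\n", psnr(rec_tv, ph),  ssim(rec_tv, ph)))
#> FBP        14.20 dB  SSIM 0.393
#> Linear+FBP 21.69 dB  SSIM 0.582
#> SART-TV    22.44 dB  SSIM 0.805
```

Direct FBP of 16 views is dominated by streaks; interpolating the missing
views first recovers 7.5 dB; TV-regularized SART trades a little PSNR
noise for much better structural similarity. Training the hybrid model on
synthetic phantoms and reconstructing with it follows the same pattern:

```r
ds    <- make_paired_dataset(100, phantom_spec(), geom, factor = 6, seed = 1)
model <- train_dual(ds, trainspec = train_spec(epochs = 20))   # ~7 min CPU
rec   <- reconstruct_dual(sparse, model)
```

An untrained model reproduces Linear+FBP exactly (residual heads start at
zero); training improves from there. `evaluate_methods()` produces the
mean PSNR/SSIM table over a test set for any mix of methods and models.

A command-line wrapper is installed at `inst/scripts/ctrecon`
(`simulate`, `train`, `reconstruct`, `evaluate`, `wavelet` subcommands,
YAML configs, JSONL logs, manifests beside every output).

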