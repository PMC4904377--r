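# csetr

Compressed-sensing reconstruction for single-axis electron tomography.

Electron tomography recovers the 3D density of a cell or tissue section from
a tilt series of STEM projections, but the mechanically limited tilt range
(a "missing wedge") and low electron dose make the inversion ill-posed.
`csetr` implements a regularized slice-wise reconstruction: each x–z slice
`f` is recovered from its sinogram `y` by approximately minimizing

    J(f) = (ν/2)·||R f − y||² + λ_TV·TV(f) + λ_I·||f||₁ + λ_W·||W f||₁

with the split Bregman method (conjugate-gradient quadratic solves
alternating with shrinkage steps), where `R` is a matched-pair discrete
Radon projector, `TV` the isotropic total variation, and `W` an orthonormal
Daubechies-8 wavelet transform. The three ℓ1 penalties express sparsity of
membranes (identity), organelle interiors (TV) and multi-scale texture
(wavelet). Weighted backprojection (WBP) and SIRT baselines, simulated
membrane/nanoparticle phantoms with calibrated Poisson–Gaussian projection
noise, compressibility metrics, and experiment harnesses (undersampling
benchmark, sparsity–error correlation, random-versus-uniform tilt sampling)
are included, together with MRC2014 / TIFF / `.rawtlt` I/O and a small CLI
(`inst/cli/cset`).

Audience: microscopists and method developers who want a self-contained,
testable reference implementation of CS-ET reconstruction and of the
phantom protocols used to characterize when compressed sensing helps.

## Worked example

Reconstruct one noisy membrane-phantom slice from a 6× undersampled ±70°
tilt series and compare with WBP:

```r
library(csetr)

vol <- make_membrane_phantom(membrane_phantom_spec(seed = 1))
slice <- vol[, 50, ]                       # one x-z slice, 256 x 256

a_full <- make_uniform_angles(70, 2)       # 71 tilts
y <- radon_forward(slice, a_full)
bg <- radon_forward(matrix(0.15, 256, 256), a_full)$data
y_noisy <- add_poisson_gaussian_noise(
  y, noise_spec(background_level = bg, seed = 11), mode = "membrane")

a6 <- undersample_angles(a_full, 6)        # 12 tilts
y6 <- sinogram(y_noisy$data[seq(1, 71, by = 6), ], a6)

w <- reg_weights(5e-6, 5e-6 * 12, 5e-6 * 60, 5e-6 * 40)
fit <- cset_reconstruct_slice(y6, c(256, 256), w)
fit
#> <recon_result> 256 x 256 image, 10 outer iterations, final ||Rf-y|| = 35.39

rmse(fit$image, slice)
#> [1] 0.2254042
rmse(wbp_reconstruct(y6, c(256, 256)), slice)
#> [1] 0.9184738
```

The CS-ET reconstruction recovers the slice with an RMSE of 0.23 (phantom
densities live in [0, 1]), four times lower than WBP's 0.92 from the same
12-projection data — the undersampling regime where sparsity-exploiting
recovery pays off most. `compressibility_ratio()` quantifies why: the slice
keeps only ~14% of its gradient-domain entries above 5% of the maximum.

For experimental data, `default_weights("bright_field", 6)` and friends
expose the published per-dataset parameter values, and
`read_tilt_series()` / `write_mrc()` handle IMOD-style aligned stacks with
side-car `.rawtlt` angle files.

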