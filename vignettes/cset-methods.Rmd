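---
title: "Compressed-sensing reconstruction for electron tomography: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compressed-sensing reconstruction for electron tomography: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(csetr)
```

## The reconstruction problem

Single-axis electron tomography acquires 2D projections of a specimen tilted
about the y-axis through a mechanically limited range (typically ±70° to
±78°), with the beam along z at zero tilt. Under linear-imaging assumptions
(valid for both bright-field and dark-field STEM of stained sections), each
projection pixel is a line integral of the 3D electron density. Because the
tilt axis is fixed, the 3D problem separates into independent 2D problems:
each x–z slice `f` (one per y index) is recovered from its own sinogram `y`
of τ tilts × σ detector bins. The limited tilt range leaves a wedge of
Fourier space unmeasured (the "missing wedge"), which degrades resolution
along z and makes the inverse problem ill-posed; undersampled tilt series
(keeping every k-th projection) make it worse.

`csetr` reconstructs each slice as the approximate minimizer of

    J(f) = (ν/2)·||R f − y||² + λ_TV·TV(f) + λ_I·||f||₁ + λ_W·||W f||₁

where `R` is the discrete Radon transform of the measurement geometry, `TV`
is the (isotropic, by default) total variation, and `W` an orthonormal
Daubechies-8 wavelet transform. The three ℓ1 terms encode three sparsity
models that cellular material plausibly satisfies in different mixtures:
membranes are sparse line-like sets in the slice itself (identity term),
organelles are piecewise-constant regions (TV term), and multi-scale texture
such as chromatin compresses well in a wavelet basis (wavelet term). Weighted
backprojection (`wbp_reconstruct()`) and SIRT (`sirt_reconstruct()`) are
provided as the conventional baselines for comparison.

## Discretization of the projector

The paper-level model leaves the discretization open; we use a Joseph-type
ray-driven projector: σ equals the image width n_x, the detector is centred
on the rotation centre with one-pixel bins, and for each ray the image is
sampled once per crossing of the more-perpendicular pixel grid, with linear
interpolation between the two adjacent pixels and a path-length weight
(1/|cos θ| for z-driven tilts). The adjoint is the exact algebraic transpose
— the same interpolation weights scattered instead of gathered — which the
conjugate-gradient inner solver requires; `tests` verify the pair against a
dense materialized operator to 1e-10.

Two consequences worth knowing. First, mass is conserved (projection row sum
= image sum) to about 1e-4 for smooth structures supported inside the
inscribed disc, but *not* for a single pixel at oblique angles, whose row sum
is the per-crossing path length (exactly 1/cos θ): path-length-weighted
interpolating projectors concentrate a point's mass on one sample per
crossing. Second, pixels whose projection falls outside the σ = n_x detector
(image corners at high tilt) are clipped, as in a real acquisition.

For iterative solves, the interpolation indices and weights are precomputed
once per (angle set, grid) pair and reused across the thousands of projector
applications of a reconstruction; the tabulated weights are stored in single
precision, which perturbs the operator by ~1e-7 relative while keeping the
forward/adjoint pair exactly matched.

## The split Bregman solver

`cset_reconstruct_slice()` follows the standard Goldstein–Osher layout,
adapted from Fourier to Radon measurements. Each ℓ1 term gets a splitting
variable and a Bregman vector (`d_TV`/`b_TV` as gradient fields with
isotropic vector shrinkage; `d_I`, `d_W` with scalar soft thresholding). The
quadratic-penalty weight of each splitting equals its λ, so the shrinkage
thresholds are 1 and a common rescaling of (ν, λ_TV, λ_I, λ_W) leaves the
iteration — and hence the minimizer — exactly invariant (verified to 1e-3 in
the tests; only the ratios λ/ν matter).

* Inner loop (12 iterations by default): solve the normal equations
  `(ν RᵀR + λ_TV ∇ᵀ∇ + (λ_I + λ_W) I) f = rhs` by conjugate gradients
  (≤10 iterations or relative residual < 1e-6, warm-started from the
  previous iterate; `WᵀW = I` because the wavelet transform is orthonormal),
  then apply the three shrinkages and Bregman-vector updates.
* Outer loop (10 iterations by default): add the data residual back to the
  measurements (`y_k ← y_k + y − R f`), progressively enforcing data
  fidelity in the Bregman sense.

Iteration counts are fixed (no adaptive stopping); initialization is zero
for the image and all auxiliary variables. There is no positivity constraint
by default; an optional clamp after the final iteration is available
(`nonnegativity = TRUE`). The solver is deterministic: identical inputs and
configuration give bitwise-identical results, which is what makes the
slice-parallel volume driver (`cset_reconstruct_volume()`) independent of
the worker count.

With only the identity penalty active and a single outer iteration, the
inner loop is plain ADMM for the penalized least-squares problem, and the
tests verify agreement with an independent proximal-gradient (ISTA) solver
to 1e-3. With all penalties at zero and a generous CG budget, the solver
matches a dense least-squares solve to 1e-3 — the two quantitative anchors
for solver correctness.

## Regularization weights

For the experimental beta-cell datasets the published parameter values are
exposed as `default_weights()`: bright field ν = 5e-6 (1×) or 1e-5 (3×, 6×)
with multiples (1.2, 6, 4); dark field ν = 1e-6 with multiples (4, 8, 10),
(6, 2, 6), (4, 2, 4) at 1×, 3×, 6×.

No weights are published for the phantom studies, and weight selection is
acknowledged to be heuristic per dataset. For the membrane/nanoparticle
phantom experiments in this package we fixed, once, ν = 5e-6 with multiples
(12, 60, 40) — the bright-field ratio pattern scaled ×10 — after a small
pilot on a single membrane slice in which reconstruction RMSE served as the
quantitative stand-in for the original visual tuning. All phantom results
(benchmarks, correlations, sampling experiments, acceptance outputs) use
this one set.

## Wavelet transform

"DB8" is read as the Daubechies wavelet with 8 vanishing moments (16-tap
filters), orthonormal with periodic boundary extension so that `Wᵀ = W⁻¹`
exactly — the property the normal operator exploits. Default depth is 4
levels. Two practical rules keep the periodized bank orthonormal: sides not
divisible by `2^levels` are symmetrically zero-padded (and cropped on
inversion), and the depth is capped so every analysis stage sees at least 16
samples — a 16-tap filter that wraps a shorter signal more than once is no
longer orthogonal. A 64×64 slice therefore decomposes to 3 levels even if 4
are requested.

## Phantoms and noise models

`make_membrane_phantom()` emulates a stained cytoplasm: a 256 × 100 × 256
voxel volume (values in [0, 1]) with a uniform 0.15 background, 40
ellipsoidal shells (membrane-bound compartments; random centres, semi-axes
4–60 px, 3D orientations, thicknesses 1–3 px) and 60 filled ellipsoids
(dense bodies, half linear scale), additive contrasts 0.2–0.85 and a final
clip to [0, 1]. Structure counts, size ranges and the background value are
not stated in the source material; these defaults were chosen once to mimic
the published phantom images and give compressibility ratios intermediate
between the nanoparticle phantom and pure noise, and they are all exposed in
`membrane_phantom_spec()`. `make_nanoparticle_phantom()` draws high-contrast
piecewise-constant discs and crescents on a zero background.

Two projection-noise models:

* **Nanoparticle mode** — scale the sinogram so its mean equals the Poisson
  rate (5,500 expected counts at the mean projection value), sample Poisson
  per entry, rescale, then add zero-mean Gaussian noise with σ = 10% of the
  projection mean. The "rate at the mean" reading is the only one that makes
  the 10% Gaussian stage commensurate with the Poisson stage.
* **Membrane mode** — Poisson only, with the count scale calibrated by
  `calibrate_membrane_noise()` so the expected per-entry noise magnitude
  averages 10% of the *background-subtracted* projection mean. The
  background reference is the projection of the uniform 0.15 slab for the
  same angle set (path length, and hence background, depends on tilt).
  Calibrating against the unsubtracted mean roughly doubles the noise and
  is enough to change qualitative outcomes — notably the sign of the 1×
  random-versus-uniform comparison below.

What these phantoms do *not* emulate: detector PSF, beam damage, alignment
error, fiducial markers, and the structural richness of real cytoplasm.
Passing the phantom suites shows the solver behaves as designed under the
stated models, not that equal gains will appear on experimental tilt series
— indeed the source study's central observation is that real biological
data, being less compressible, benefit less from undersampled CS recovery.

## Evaluation protocol

Compressibility is measured by the n%-compressibility ratio
(`compressibility_ratio()`): the fraction of transform-domain entries with
magnitude above n% of the largest. Identity-domain ratios of membrane-like
images are computed after background subtraction — with a 0.15 background
every pixel of every slice clears a 5% threshold, saturating the ratio at 1
— matching the background-subtraction step prescribed for experimental
identity-sparsity analysis. RMSE on phantoms is computed in phantom units
without whitening; `whiten()` (zero mean, unit variance) is for
experimental-style comparisons where absolute scale is arbitrary.

The benchmark and experiment harnesses fix these problem sizes, chosen as
the package's study conditions:

* `undersampling_benchmark()` on 8 x–z slices (y = 8 … 96, evenly spaced) of
  the seeded default phantom, noisy, at 1×/3×/6× (71/24/12 tilts of the
  ±70°, 2° series). Expected behaviour: CS-ET beats WBP at every level and
  the CS-ET/WBP RMSE ratio shrinks monotonically with undersampling.
* Sparsity–error association on the same slices: Pearson r between
  truth-slice 5% ratios and per-slice CS-ET RMSE at 6×, positive in all
  three domains.
* `sampling_comparison_experiment()` on a 4×-downsampled (64×64) central
  slice: per trial, a fresh uniform-random angle set versus the uniform grid
  of equal size, identical noise protocol, RMSE difference random − uniform.
  15 trials at the full tilt count and 10 at 6× — the full-series effect is
  an order of magnitude smaller (clumping matters less when sampling is
  dense), so it gets more trials. Expected: positive mean difference in all
  four conditions (noisy/noiseless × 1×/6×), i.e. random sampling does not
  pay in parallel-beam tomography.
* Nanoparticle check: noiseless 3× recovery; CS-ET RMSE at most half of
  WBP's.

These sizes keep the whole acceptance analysis within a desk-scale compute
budget while preserving every qualitative contrast; `scripts/acceptance.R`
re-runs all of them from scratch and writes the numbers as JSON.

## Numerical choices and degenerate inputs

* CG stops on `denom ≤ 0` (semi-definite safeguard) or non-finite iterates
  (reported as an error naming the iteration).
* An all-zero sinogram reconstructs to the zero image with zero traces, for
  every method.
* SIRT replaces zero row/column normalization sums by zero weights rather
  than erroring (rays that miss the grid contribute nothing).
* WBP's ramp filter runs on rows zero-padded to the next power of two ≥ 2σ;
  `ram-lak` is the default, `hamming` available, `none` reduces to plain
  backprojection. Backprojection is pixel-driven with linear interpolation,
  scaled by π/(2τ).
* `soft_threshold(x, 0)` is the identity; `vector_shrink` maps zero-norm
  pixels to zero.
* Whitening a constant volume, compressibility of an all-zero image, and a
  zero reference ratio in `rho_distribution()` raise degenerate-input
  errors rather than returning NaN.
* Random angle sets are sorted and may contain duplicates (a measure-zero
  event under the uniform law); they are not deduplicated.
* All randomized operations (angle draws, phantoms, noise) take explicit
  seeds, restore the caller's RNG state, and are bitwise reproducible.

## Known limitations

* Fan/cone-beam and dual-axis geometries are out of scope; so are
  Fourier-domain (NUFFT) solver variants and fully-3D joint regularization.
* The per-slice 2D decomposition ignores correlations between adjacent x–z
  slices that a fully-3D prior would exploit.
* The split Bregman iteration with fixed counts is an early-stopped scheme;
  its output is not the exact minimizer of J (the tests that need the
  minimizer run the solver to convergence with enlarged budgets).
* The projector's finite detector clips corner mass at high tilt; phantoms
  whose structures hug the slice corners will show small systematic
  projection deficits.
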