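#' Root mean squared error between two images or volumes
#'
#' `sqrt(mean((a - b)^2))` over all elements; a metric (symmetric,
#' nonnegative, zero iff equal).
#'
#' @param a,b congruent numeric arrays.
#' @return scalar RMSE.
#' @export
rmse <- function(a, b) {
  if (!isTRUE(all.equal(dim(a) %||% length(a), dim(b) %||% length(b))))
    stop_invalid("inputs must have congruent shapes")
  sqrt(mean((a - b)^2))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Whiten a volume to zero mean and unit variance
#'
#' Population-variance convention; idempotent and invariant to affine
#' rescaling with positive slope. Used before comparing reconstructions of
#' experimental data whose absolute intensity scale is arbitrary.
#'
#' @param v numeric array (non-constant).
#' @return whitened array of the same shape.
#' @export
whiten <- function(v) {
  mu <- mean(v)
  s2 <- mean((v - mu)^2)
  if (s2 == 0) stop_degenerate("constant volume cannot be whitened")
  (v - mu) / sqrt(s2)
}

#' Estimate a background level from image patches
#'
#' Mean over the union of rectangular patches (the manual background-patch
#' protocol for identity-domain sparsity of experimental reconstructions).
#'
#' @param f slice matrix.
#' @param patches list of patches, each `c(x0, x1, z0, z1)` (inclusive,
#'   1-based).
#' @return scalar mean background value.
#' @export
estimate_background <- function(f, patches) {
  f <- as.matrix(f)
  if (length(patches) == 0) stop_invalid("need at least one patch")
  mask <- matrix(FALSE, nrow(f), ncol(f))
  for (p in patches) {
    if (length(p) != 4 || p[1] < 1 || p[3] < 1 || p[2] > nrow(f) ||
        p[4] > ncol(f) || p[1] > p[2] || p[3] > p[4])
      stop_invalid("patch out of bounds: ", paste(p, collapse = ","))
    mask[p[1]:p[2], p[3]:p[4]] <- TRUE
  }
  mean(f[mask])
}

#' Per-slice sparsity versus reconstruction error
#'
#' For each slice, the n%-compressibility ratio of the ground-truth phantom
#' slice in the requested transform domain, the RMSE of its reconstruction,
#' and the Pearson correlation between the two across slices — the
#' association underlying the claim that CS reconstruction quality tracks
#' signal compressibility.
#'
#' @param recons list of reconstructed slice matrices.
#' @param truth list of matching ground-truth slices (or a 3D array whose
#'   y-slices match).
#' @param n_percent relative compressibility threshold in percent.
#' @param domain `"TV"`, `"identity"` or `"wavelet"`.
#' @return list with `table` (data.frame: slice, ratio, rmse) and
#'   `pearson_r` (`NA` with a `degenerate` flag when error variance is zero).
#' @export
sparsity_error_table <- function(recons, truth, n_percent = 5,
                                 domain = c("TV", "identity", "wavelet")) {
  domain <- match.arg(domain)
  if (is.array(truth) && length(dim(truth)) == 3)
    truth <- lapply(seq_len(dim(truth)[2]), function(i) truth[, i, ])
  if (length(recons) != length(truth))
    stop_invalid("slice counts must match")
  if (length(recons) < 3)
    stop_invalid("need at least 3 slices for a correlation")
  ratio <- vapply(truth, compressibility_ratio, numeric(1),
                  n_percent = n_percent, domain = domain)
  err <- mapply(function(r, t) rmse(r, t), recons, truth)
  degenerate <- sd(err) == 0 || sd(ratio) == 0
  r <- if (degenerate) NA_real_ else cor(ratio, err)
  list(table = data.frame(slice = seq_along(recons), ratio = ratio, rmse = err),
       pearson_r = r, degenerate = degenerate)
}

#' Relative compressibility distribution (rho)
#'
#' For each test slice, `rho` is its n%-compressibility ratio divided by the
#' mean ratio of the reference slices; reported with the per-domain mean and
#' standard deviation. `rho > 1` means the test data are less compressible
#' than the reference.
#'
#' @param test_slices list of slice matrices under assessment.
#' @param ref_slices list of reference slice matrices.
#' @param n_percent relative threshold in percent (2.5 in the experimental
#'   comparison protocol).
#' @param domain `"TV"`, `"identity"` or `"wavelet"`.
#' @return a `sparsity_report`: data.frame of per-slice rho plus a
#'   `rho_summary` attribute `c(mean, sd)`.
#' @export
rho_distribution <- function(test_slices, ref_slices, n_percent = 2.5,
                             domain = c("TV", "identity", "wavelet")) {
  domain <- match.arg(domain)
  if (length(test_slices) == 0 || length(ref_slices) == 0)
    stop_invalid("both slice sets must be non-empty")
  ref_ratio <- mean(vapply(ref_slices, compressibility_ratio, numeric(1),
                           n_percent = n_percent, domain = domain))
  if (ref_ratio == 0) stop_degenerate("reference compressibility ratio is zero")
  rho <- vapply(test_slices, compressibility_ratio, numeric(1),
                n_percent = n_percent, domain = domain) / ref_ratio
  out <- data.frame(slice = seq_along(test_slices), domain = domain,
                    n_percent = n_percent, rho = rho)
  attr(out, "rho_summary") <- c(mean = mean(rho), sd = sd(rho))
  class(out) <- c("sparsity_report", "data.frame")
  out
}

#' Random-versus-uniform tilt sampling experiment
#'
#' For each trial, reconstructs the phantom slices by CS-ET from a fresh
#' random angle set and from the fixed uniform angle set of equal size
#' (identical noise protocol for both), and returns the per-trial difference
#' `rmse_random - rmse_uniform`; positive values mean random sampling
#' performed worse.
#'
#' @param slices list of ground-truth slice matrices (x-z slices).
#' @param n_tilts number of tilts per angle set.
#' @param max_tilt half-range of the tilt series in degrees.
#' @param n_trials number of random-angle trials.
#' @param noise a [noise_spec()] plus noise `mode`, or `NULL` for noiseless
#'   projections.
#' @param noise_mode `"membrane"` or `"nanoparticle"` (when `noise` given).
#' @param background_density scalar phantom background density; when given
#'   (membrane mode), the projection-domain background used for noise
#'   calibration is recomputed as the projection of a uniform slab at this
#'   density for each trial's angle set.
#' @param w a `reg_weights` object.
#' @param cfg a `solver_config`.
#' @param seed master seed; trial angle seeds and noise seeds derive from it.
#' @return data.frame with per-trial `rmse_random`, `rmse_uniform`, `diff`.
#' @export
sampling_comparison_experiment <- function(slices, n_tilts, max_tilt = 70,
                                           n_trials = 10, noise = NULL,
                                           noise_mode = "membrane",
                                           background_density = NULL,
                                           w = default_weights(), cfg = solver_config(),
                                           seed = 1) {
  if (n_trials < 1) stop_invalid("n_trials must be >= 1")
  if (n_tilts < 2) stop_invalid("need at least two tilts")
  shape <- dim(slices[[1]])
  uni <- make_uniform_angles(max_tilt, 2 * max_tilt / (n_tilts - 1))
  stopifnot(length(uni) == n_tilts)

  run_volume <- function(a, noise_seed) {
    bg <- if (!is.null(noise) && !is.null(background_density))
      radon_forward(matrix(background_density, shape[1], shape[2]), a)$data
    errs <- vapply(seq_along(slices), function(i) {
      y <- radon_forward(slices[[i]], a)
      if (!is.null(noise)) {
        ns <- noise
        ns$seed <- noise_seed + i
        if (!is.null(background_density)) ns$background_level <- bg
        y <- add_poisson_gaussian_noise(y, ns, mode = noise_mode)
      }
      fhat <- cset_reconstruct_slice(y, shape, w, cfg)$image
      sum((fhat - slices[[i]])^2)
    }, numeric(1))
    sqrt(sum(errs) / (length(slices) * prod(shape)))
  }

  # noiseless uniform baseline is deterministic across trials: compute once
  uni_fixed <- if (is.null(noise)) run_volume(uni, 0L) else NULL
  res <- lapply(seq_len(n_trials), function(tr) {
    trial_seed <- seed * 1000L + tr
    a_rand <- make_random_angles(n_tilts, max_tilt, seed = trial_seed)
    c(rmse_random = run_volume(a_rand, trial_seed),
      rmse_uniform = uni_fixed %||% run_volume(uni, trial_seed))
  })
  out <- as.data.frame(do.call(rbind, res))
  out$trial <- seq_len(n_trials)
  out$diff <- out$rmse_random - out$rmse_uniform
  out[, c("trial", "rmse_random", "rmse_uniform", "diff")]
}

#' Undersampling benchmark: CS-ET against WBP (and optionally SIRT)
#'
#' The phantom-study comparison protocol: for each undersampling factor k,
#' every slice is projected over the full uniform tilt series, membrane-mode
#' Poisson noise is (optionally) added, every k-th projection is kept, and
#' the slice is reconstructed with CS-ET, WBP and (optionally) SIRT. Returns
#' per-slice, per-method RMSE against the ground-truth slices.
#'
#' @param slices list of ground-truth x-z slice matrices.
#' @param w a `reg_weights` object for the CS-ET reconstructions.
#' @param undersampling integer undersampling factors (default `c(1, 3, 6)`).
#' @param max_tilt,increment uniform tilt scheme of the full series (degrees).
#' @param noise a [noise_spec()] or `NULL` for noiseless projections
#'   (membrane-mode noise; the background projection for calibration is the
#'   projection of a uniform `background_density` slab).
#' @param background_density scalar background density of the phantom.
#' @param cfg a `solver_config`.
#' @param sirt include SIRT reconstructions.
#' @param seed seed for the per-slice noise realizations.
#' @return data.frame with columns `k`, `slice`, `method`, `rmse`.
#' @export
undersampling_benchmark <- function(slices, w, undersampling = c(1, 3, 6),
                                    max_tilt = 70, increment = 2,
                                    noise = NULL, background_density = 0.15,
                                    cfg = solver_config(), sirt = FALSE,
                                    seed = 1) {
  a_full <- make_uniform_angles(max_tilt, increment)
  shape <- dim(slices[[1]])
  bg <- if (!is.null(noise))
    radon_forward(matrix(background_density, shape[1], shape[2]), a_full)$data
  sinos <- lapply(seq_along(slices), function(i) {
    y <- radon_forward(slices[[i]], a_full)
    if (!is.null(noise)) {
      ns <- noise
      ns$seed <- seed * 100L + i
      ns$background_level <- bg
      y <- add_poisson_gaussian_noise(y, ns, mode = "membrane")
    }
    y
  })
  rows <- list()
  for (k in undersampling) {
    idx <- seq(1, length(a_full), by = k)
    ak <- undersample_angles(a_full, k)
    for (i in seq_along(slices)) {
      yk <- sinogram(sinos[[i]]$data[idx, , drop = FALSE], ak)
      recs <- list(
        cset = cset_reconstruct_slice(yk, shape, w, cfg)$image,
        wbp = wbp_reconstruct(yk, shape))
      if (sirt) recs$sirt <- sirt_reconstruct(yk, shape)
      for (m in names(recs))
        rows[[length(rows) + 1]] <- data.frame(
          k = k, slice = i, method = m, rmse = rmse(recs[[m]], slices[[i]]))
    }
  }
  do.call(rbind, rows)
}
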