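#' Regularization weights for the CS-ET objective
#'
#' The objective is
#' `J(f) = (nu/2) ||Rf - y||^2 + lambda_tv TV(f) + lambda_i ||f||_1 +
#' lambda_w ||Wf||_1`. The lambdas are conventionally expressed as multiples
#' of the data-fidelity weight `nu`; only the ratios `lambda / nu` affect the
#' minimizer (a common rescaling of all four weights leaves it unchanged).
#'
#' @param nu data-fidelity weight, > 0.
#' @param lambda_tv,lambda_i,lambda_w l1 weights for the TV, identity and
#'   wavelet penalties, >= 0 (at least one positive for CS reconstruction).
#' @return a `reg_weights` object.
#' @export
reg_weights <- function(nu, lambda_tv = 0, lambda_i = 0, lambda_w = 0) {
  if (!is.finite(nu) || nu <= 0) stop_invalid("nu must be positive")
  l <- c(lambda_tv, lambda_i, lambda_w)
  if (any(!is.finite(l)) || any(l < 0)) stop_invalid("lambdas must be >= 0")
  structure(list(nu = nu, lambda_tv = lambda_tv, lambda_i = lambda_i,
                 lambda_w = lambda_w), class = "reg_weights")
}

#' Published weight presets for experimental STEM datasets
#'
#' Data-fidelity and l1 weights used for the bright-field and dark-field
#' beta-cell reconstructions at each undersampling level. Bright field:
#' `nu = 5e-6` at 1x and `1e-5` at 3x/6x, with `(lambda_tv, lambda_i,
#' lambda_w) = nu * (1.2, 6, 4)` throughout. Dark field: `nu = 1e-6` at all
#' levels with multiples `(4, 8, 10)`, `(6, 2, 6)` and `(4, 2, 4)` at 1x,
#' 3x and 6x.
#'
#' @param modality `"bright_field"` or `"dark_field"`.
#' @param undersampling 1, 3 or 6.
#' @return a `reg_weights` object.
#' @export
default_weights <- function(modality = c("bright_field", "dark_field"),
                            undersampling = 1) {
  modality <- match.arg(modality)
  if (!undersampling %in% c(1, 3, 6))
    stop_invalid("undersampling must be one of 1, 3, 6")
  k <- as.character(undersampling)
  if (modality == "bright_field") {
    nu <- c(`1` = 5e-6, `3` = 1e-5, `6` = 1e-5)[[k]]
    mult <- c(1.2, 6, 4)
  } else {
    nu <- 1e-6
    mult <- switch(k, `1` = c(4, 8, 10), `3` = c(6, 2, 6), `6` = c(4, 2, 4))
  }
  reg_weights(nu, nu * mult[1], nu * mult[2], nu * mult[3])
}

#' Split Bregman solver configuration
#'
#' @param outer_iters Bregman (add-back) iterations, default 10.
#' @param inner_iters alternating solve/shrink iterations per outer, default 12.
#' @param cg_iters conjugate-gradient budget per quadratic subproblem.
#' @param cg_tol relative residual tolerance for CG.
#' @param tv_mode `"isotropic"` or `"anisotropic"` TV shrinkage.
#' @param wavelet_levels decomposition depth for the wavelet penalty.
#' @param nonnegativity clamp negative values after the final iteration.
#' @param seed recorded seed (the solver itself is deterministic).
#' @return a `solver_config` object.
#' @export
solver_config <- function(outer_iters = 10, inner_iters = 12, cg_iters = 10,
                          cg_tol = 1e-6, tv_mode = c("isotropic", "anisotropic"),
                          wavelet_levels = 4, nonnegativity = FALSE,
                          seed = NULL) {
  tv_mode <- match.arg(tv_mode)
  cnt <- c(outer_iters, inner_iters, cg_iters, wavelet_levels)
  if (any(!is.finite(cnt)) || any(cnt < 1))
    stop_invalid("iteration counts and wavelet levels must be >= 1")
  if (!is.finite(cg_tol) || cg_tol <= 0) stop_invalid("cg_tol must be positive")
  structure(list(outer_iters = outer_iters, inner_iters = inner_iters,
                 cg_iters = cg_iters, cg_tol = cg_tol, tv_mode = tv_mode,
                 wavelet_levels = wavelet_levels,
                 nonnegativity = isTRUE(nonnegativity), seed = seed),
            class = "solver_config")
}

#' Conjugate-gradient solve of the quadratic subproblem
#'
#' Solves `A f = rhs` with the symmetric positive (semi)definite normal
#' operator `A = nu R^T R + lambda_tv (-div grad) + (lambda_i + lambda_w) I`
#' (the wavelet penalty contributes an identity because `W^T W = I`).
#' Stops after `cg_iters` steps or when the relative residual drops below
#' `cg_tol`; warm-started from `warm_start`.
#'
#' @param rhs right-hand side, a slice-shaped matrix.
#' @param w a `reg_weights` object.
#' @param angles an `angle_set` defining `R` (or `NULL` to drop the data
#'   term, for testing).
#' @param cfg a `solver_config`.
#' @param warm_start initial iterate (defaults to zero).
#' @param apply_A optional custom operator, overriding the default normal
#'   operator (used by test harnesses).
#' @return the CG iterate, a matrix shaped like `rhs`.
#' @export
solve_quadratic_subproblem <- function(rhs, w, angles = NULL, cfg = solver_config(),
                                       warm_start = NULL, apply_A = NULL) {
  if (any(!is.finite(rhs))) stop_invalid("rhs must be finite")
  shape <- dim(rhs)
  if (is.null(apply_A)) {
    th <- if (is.null(angles)) NULL else angles$angles_deg
    lam_id <- w$lambda_i + w$lambda_w
    apply_A <- function(f) {
      out <- lam_id * f
      if (w$lambda_tv > 0) out <- out - w$lambda_tv * div2d(grad2d(f))
      if (!is.null(th) && w$nu > 0)
        out <- out + w$nu * cpp_radon_adjoint(
          cpp_radon_forward(f, th), shape[1], shape[2], th)
      out
    }
  }
  f <- if (is.null(warm_start)) matrix(0, shape[1], shape[2]) else warm_start
  r <- rhs - apply_A(f)
  nrhs <- sqrt(sum(rhs^2))
  if (nrhs == 0) nrhs <- 1
  p <- r
  rs <- sum(r^2)
  for (it in seq_len(cfg$cg_iters)) {
    if (sqrt(rs) / nrhs < cfg$cg_tol) break
    Ap <- apply_A(p)
    denom <- sum(p * Ap)
    if (!is.finite(denom) || denom <= 0) break
    alpha <- rs / denom
    f <- f + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(r^2)
    if (!all(is.finite(f)))
      stop("CG breakdown: non-finite iterate at iteration ", it)
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  f
}

#' CS-ET reconstruction of a single x-z slice
#'
#' Approximately minimizes
#' `J(f) = (nu/2) ||Rf - y||^2 + lambda_tv TV(f) + lambda_i ||f||_1 +
#' lambda_w ||Wf||_1` by the split Bregman method: one splitting variable and
#' Bregman vector per l1 term (vector shrinkage for isotropic TV, soft
#' thresholding for the identity and wavelet terms), an inner loop
#' alternating a conjugate-gradient quadratic solve with the shrinkages, and
#' an outer Bregman loop that adds the data residual back to the
#' measurements. Deterministic for fixed inputs and configuration.
#'
#' @param y a `sinogram` (the measurements).
#' @param shape reconstruction dimensions `c(n_x, n_z)`; `n_x` must equal
#'   the detector bin count.
#' @param w a `reg_weights` object.
#' @param cfg a `solver_config`.
#' @return a `recon_result`: list with `image` (the reconstruction),
#'   `objective_trace` and `data_residual_trace` (one value per outer
#'   iteration), and echoes of `weights` and `config`.
#' @export
cset_reconstruct_slice <- function(y, shape, w, cfg = solver_config()) {
  stopifnot(inherits(y, "sinogram"), inherits(w, "reg_weights"))
  if (length(shape) != 2 || any(shape < 2))
    stop_invalid("shape must be two dimensions >= 2")
  if (ncol(y$data) != shape[1])
    stop_invalid("detector bin count (", ncol(y$data),
                 ") must equal n_x (", shape[1], ")")
  th <- y$angles$angles_deg
  nx <- as.integer(shape[1]); nz <- as.integer(shape[2])
  plan <- cpp_radon_plan(nx, nz, th)
  R_fwd <- function(fm) cpp_radon_forward_plan(fm, plan)
  R_adj <- function(ym) cpp_radon_adjoint_plan(ym, plan)
  use_tv <- w$lambda_tv > 0
  use_i <- w$lambda_i > 0
  use_w <- w$lambda_w > 0

  f <- matrix(0, nx, nz)
  zero_field <- structure(list(gx = f, gz = f), class = "gradient_field")
  d_tv <- b_tv <- zero_field
  d_i <- b_i <- f
  wtpl <- if (use_w) wavelet_forward(f, levels = cfg$wavelet_levels) else NULL
  zero_w <- if (use_w) as.vector(wtpl) else NULL
  d_w <- b_w <- zero_w

  yk <- y$data
  obj_trace <- res_trace <- numeric(cfg$outer_iters)
  lam_id <- w$lambda_i + w$lambda_w

  apply_A <- function(fm) {
    out <- lam_id * fm
    if (use_tv) out <- out - w$lambda_tv * div2d(grad2d(fm))
    out + w$nu * R_adj(R_fwd(fm))
  }

  for (outer in seq_len(cfg$outer_iters)) {
    rhs_data <- w$nu * R_adj(yk)   # fixed within the inner loop
    for (inner in seq_len(cfg$inner_iters)) {
      rhs <- rhs_data
      if (use_tv) {
        dd <- structure(list(gx = d_tv$gx - b_tv$gx, gz = d_tv$gz - b_tv$gz),
                        class = "gradient_field")
        rhs <- rhs - w$lambda_tv * div2d(dd)   # grad^T = -div
      }
      if (use_i) rhs <- rhs + w$lambda_i * (d_i - b_i)
      if (use_w) {
        wc <- wavelet_from_vector(d_w - b_w, wtpl)
        rhs <- rhs + w$lambda_w * wavelet_inverse(wc)   # W^T = W^-1
      }
      f <- solve_quadratic_subproblem(rhs, w, cfg = cfg, warm_start = f,
                                      apply_A = apply_A)
      if (use_tv) {
        g <- grad2d(f)
        v <- structure(list(gx = g$gx + b_tv$gx, gz = g$gz + b_tv$gz),
                       class = "gradient_field")
        d_tv <- if (cfg$tv_mode == "isotropic") vector_shrink(v, 1)
                else structure(list(gx = soft_threshold(v$gx, 1),
                                    gz = soft_threshold(v$gz, 1)),
                               class = "gradient_field")
        b_tv <- structure(list(gx = v$gx - d_tv$gx, gz = v$gz - d_tv$gz),
                          class = "gradient_field")
      }
      if (use_i) {
        v <- f + b_i
        d_i <- soft_threshold(v, 1)
        b_i <- v - d_i
      }
      if (use_w) {
        v <- as.vector(wavelet_forward(f, levels = cfg$wavelet_levels)) + b_w
        d_w <- soft_threshold(v, 1)
        b_w <- v - d_w
      }
    }
    rf <- R_fwd(f)
    yk <- yk + (y$data - rf)
    res_trace[outer] <- sqrt(sum((rf - y$data)^2))
    obj_trace[outer] <- (w$nu / 2) * res_trace[outer]^2 +
      (if (use_tv) w$lambda_tv * tv_norm(f, cfg$tv_mode) else 0) +
      (if (use_i) w$lambda_i * sum(abs(f)) else 0) +
      (if (use_w) w$lambda_w *
         sum(abs(as.vector(wavelet_forward(f, levels = cfg$wavelet_levels))))
       else 0)
  }
  if (cfg$nonnegativity) f <- pmax(f, 0)
  structure(list(image = f, objective_trace = obj_trace,
                 data_residual_trace = res_trace, weights = w, config = cfg),
            class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf("<recon_result> %d x %d image, %d outer iterations, final ||Rf-y|| = %.4g\n",
              nrow(x$image), ncol(x$image), length(x$objective_trace),
              x$data_residual_trace[length(x$data_residual_trace)]))
  invisible(x)
}

#' CS-ET reconstruction of a volume, slice by slice
#'
#' Applies [cset_reconstruct_slice()] independently to the sinogram of each
#' x-z slice (one per y index). Because each per-slice solve is
#' deterministic, the result does not depend on how the work is scheduled.
#'
#' @param tilt_stack list of `sinogram` objects, one per y-slice, sharing a
#'   common angle set and detector size.
#' @param shape slice dimensions `c(n_x, n_z)`.
#' @param w a `reg_weights` object.
#' @param cfg a `solver_config`.
#' @param workers number of worker processes (slice-parallel via forking
#'   where available; 1 = sequential).
#' @return list with `volume` (an `n_x x n_y x n_z` array) and `diagnostics`
#'   (per-slice objective and residual traces).
#' @export
cset_reconstruct_volume <- function(tilt_stack, shape, w, cfg = solver_config(),
                                    workers = 1) {
  stopifnot(is.list(tilt_stack), length(tilt_stack) >= 1)
  a0 <- tilt_stack[[1]]$angles$angles_deg
  for (s in tilt_stack) {
    if (!inherits(s, "sinogram")) stop_invalid("tilt_stack must hold sinograms")
    if (!isTRUE(all.equal(s$angles$angles_deg, a0)) ||
        ncol(s$data) != ncol(tilt_stack[[1]]$data))
      stop_invalid("all sinograms must share one angle set and detector size")
  }
  run1 <- function(s) cset_reconstruct_slice(s, shape, w, cfg)
  res <- if (workers > 1 && .Platform$OS.type == "unix") {
    parallel::mclapply(tilt_stack, run1, mc.cores = workers)
  } else lapply(tilt_stack, run1)
  vol <- array(0, dim = c(shape[1], length(tilt_stack), shape[2]))
  for (i in seq_along(res)) vol[, i, ] <- res[[i]]$image
  diag <- lapply(res, function(r)
    list(objective_trace = r$objective_trace,
         data_residual_trace = r$data_residual_trace))
  list(volume = vol, diagnostics = diag)
}
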