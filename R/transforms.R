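#' Forward-difference gradient of a slice
#'
#' Forward differences along x (rows) and z (columns) with replicate
#' (Neumann) boundaries, so the difference at the far boundary is zero.
#' Linear in `f`; the negative adjoint is [div2d()].
#'
#' @param f slice matrix.
#' @return a `gradient_field`: list with matrices `gx`, `gz` congruent
#'   with `f`.
#' @export
grad2d <- function(f) {
  f <- check_slice(f)
  nx <- nrow(f); nz <- ncol(f)
  gx <- rbind(f[-1, , drop = FALSE] - f[-nx, , drop = FALSE],
              matrix(0, 1, nz))
  gz <- cbind(f[, -1, drop = FALSE] - f[, -nz, drop = FALSE],
              matrix(0, nx, 1))
  structure(list(gx = gx, gz = gz), class = "gradient_field")
}

#' Discrete divergence (negative adjoint of grad2d)
#'
#' Satisfies `<grad2d(f), g> = -<f, div2d(g)>` exactly, which the
#' conjugate-gradient normal operator of the solver relies on
#' (`-div(grad(.))` is symmetric positive semidefinite).
#'
#' @param g a `gradient_field`.
#' @return slice matrix congruent with the field components.
#' @export
div2d <- function(g) {
  stopifnot(inherits(g, "gradient_field"))
  gx <- g$gx; gz <- g$gz
  if (!all(dim(gx) == dim(gz))) stop_invalid("field components must be congruent")
  nx <- nrow(gx); nz <- ncol(gx)
  # adjoint of the forward difference: the far-boundary component of the
  # field is structurally zero in the range of grad2d, so it is ignored
  # (zeroed) here; (div g)_i = g_i - g_{i-1} with g_0 = 0.
  gx[nx, ] <- 0
  gz[, nz] <- 0
  dx <- gx - rbind(matrix(0, 1, nz), gx[-nx, , drop = FALSE])
  dz <- gz - cbind(matrix(0, nx, 1), gz[, -nz, drop = FALSE])
  dx + dz
}

#' Total variation of a slice
#'
#' Isotropic (default): sum over pixels of `sqrt(gx^2 + gz^2)`;
#' anisotropic: sum of `|gx| + |gz|`. Zero iff the slice is constant.
#'
#' @param f slice matrix.
#' @param mode `"isotropic"` or `"anisotropic"`.
#' @return scalar TV value.
#' @export
tv_norm <- function(f, mode = c("isotropic", "anisotropic")) {
  mode <- match.arg(mode)
  g <- grad2d(f)
  if (mode == "isotropic") sum(sqrt(g$gx^2 + g$gz^2))
  else sum(abs(g$gx)) + sum(abs(g$gz))
}

# Daubechies-8 (eight vanishing moments, 16-tap) orthonormal filter bank.
DB8_LO <- c(-1.17476784124769535e-04, 6.75449406450569331e-04,
            -3.91740373376947050e-04, -4.87035299345157414e-03,
            8.74609404740577662e-03, 1.39810279173982824e-02,
            -4.40882539307947546e-02, -1.73693010018075474e-02,
            1.28747426620478472e-01, 4.72484573913282795e-04,
            -2.84015542961546907e-01, -1.58291052563493059e-02,
            5.85354683654206731e-01, 6.75630736297289758e-01,
            3.12871590914299946e-01, 5.44158422431040081e-02)
DB8_HI <- rev(DB8_LO) * rep_len(c(1, -1), length(DB8_LO))

# Periodic (circular) analysis step for every column of a matrix:
# a[k] = sum_j lo[j] m[(2k + j) mod n] and likewise for the detail band
# (compiled kernel; the synthesis is its exact transpose, hence the inverse
# for an orthonormal filter bank).
dwt_cols <- function(m, lo, hi) {
  out <- cpp_dwt_cols(m, lo, hi)
  nh <- nrow(m) / 2
  list(a = out[seq_len(nh), , drop = FALSE],
       d = out[nh + seq_len(nh), , drop = FALSE])
}

idwt_cols <- function(a, d, lo, hi) {
  cpp_idwt_cols(rbind(a, d), lo, hi)
}

pad_to_size <- function(f, tx, tz) {
  nx <- nrow(f); nz <- ncol(f)
  if (tx == nx && tz == nz)
    return(list(f = f, orig = c(nx, nz), off = c(0L, 0L)))
  g <- matrix(0, tx, tz)
  ox <- floor((tx - nx) / 2); oz <- floor((tz - nz) / 2)
  g[ox + seq_len(nx), oz + seq_len(nz)] <- f
  list(f = g, orig = c(nx, nz), off = c(ox, oz))
}

# Deepest decomposition level at which the periodic 16-tap filter does not
# wrap around the signal more than once (analysis length >= 16 at every
# level); below that the periodized bank is no longer orthonormal.
max_wavelet_levels <- function(n) max(0L, floor(log2(n / 16)) + 1L)

#' Multi-level 2D Daubechies-8 wavelet transform
#'
#' Orthonormal separable decomposition with periodic boundary extension, so
#' the transform is square and satisfies `W^T W = I` (energy preserved;
#' exact inversion by [wavelet_inverse()]). Slices whose sides are not
#' divisible by `2^levels` are symmetrically zero-padded to the next
#' multiple (`pad = TRUE`) or rejected.
#'
#' @param f slice matrix.
#' @param levels decomposition depth (default 4).
#' @param pad zero-pad non-divisible dimensions instead of erroring.
#' @return a `wavelet_coeffs` object; `as.vector()` flattens all
#'   coefficients.
#' @export
wavelet_forward <- function(f, levels = 4, pad = TRUE) {
  f <- check_slice(f)
  # cap the depth so every periodic analysis stage sees >= 16 samples
  # (orthonormality of the periodized bank); tiny slices are padded to 16.
  levels <- min(levels, max(1L, max_wavelet_levels(max(16, min(dim(f))))))
  m <- 2^levels
  tx <- max(16, m * ceiling(nrow(f) / m))
  tz <- max(16, m * ceiling(ncol(f) / m))
  if ((tx != nrow(f) || tz != ncol(f)) && !pad)
    stop_invalid("dimensions must be divisible by 2^levels and >= 16 ",
                 "(or set pad = TRUE)")
  p <- pad_to_size(f, tx, tz)
  cur <- p$f
  detail <- vector("list", levels)
  for (l in seq_len(levels)) {
    cc <- dwt_cols(cur, DB8_LO, DB8_HI)              # along x (rows)
    ar <- dwt_cols(t(cc$a), DB8_LO, DB8_HI)          # along z
    dr <- dwt_cols(t(cc$d), DB8_LO, DB8_HI)
    cur <- t(ar$a)
    detail[[l]] <- list(lh = t(ar$d), hl = t(dr$a), hh = t(dr$d))
  }
  structure(list(approx = cur, detail = detail, levels = levels,
                 padded_dim = dim(p$f), orig_dim = p$orig, off = p$off),
            class = "wavelet_coeffs")
}

#' Inverse 2D Daubechies-8 wavelet transform
#'
#' Exact inverse (= adjoint, by orthonormality) of [wavelet_forward()];
#' padding introduced there is cropped away.
#'
#' @param c a `wavelet_coeffs` object.
#' @return the reconstructed slice matrix.
#' @export
wavelet_inverse <- function(c) {
  if (!inherits(c, "wavelet_coeffs")) stop_invalid("expected wavelet_coeffs")
  cur <- c$approx
  for (l in rev(seq_len(c$levels))) {
    d <- c$detail[[l]]
    if (is.null(d$lh) || is.null(d$hl) || is.null(d$hh) ||
        !all(dim(d$lh) == dim(cur)))
      stop_invalid("corrupted coefficient layout at level ", l)
    a_col <- t(idwt_cols(t(cur), t(d$lh), DB8_LO, DB8_HI))
    d_col <- t(idwt_cols(t(d$hl), t(d$hh), DB8_LO, DB8_HI))
    cur <- idwt_cols(a_col, d_col, DB8_LO, DB8_HI)
  }
  ox <- c$off[1]; oz <- c$off[2]
  cur[ox + seq_len(c$orig_dim[1]), oz + seq_len(c$orig_dim[2]), drop = FALSE]
}

#' @export
as.vector.wavelet_coeffs <- function(x, mode = "any") {
  c(as.vector(x$approx),
    unlist(lapply(x$detail, function(d) c(d$lh, d$hl, d$hh)), use.names = FALSE))
}

# Rebuild a wavelet_coeffs object from a flat vector with the layout of `tpl`.
wavelet_from_vector <- function(v, tpl) {
  n <- length(tpl$approx)
  tplv <- tpl
  tplv$approx <- matrix(v[seq_len(n)], nrow(tpl$approx))
  pos <- n
  for (l in seq_len(tpl$levels)) {
    for (band in c("lh", "hl", "hh")) {
      b <- tpl$detail[[l]][[band]]
      m <- length(b)
      tplv$detail[[l]][[band]] <- matrix(v[pos + seq_len(m)], nrow(b))
      pos <- pos + m
    }
  }
  tplv
}

#' Soft thresholding (scalar shrinkage)
#'
#' `sign(x) * max(|x| - t, 0)`, elementwise — the proximal operator of the
#' l1 norm and the shrinkage step of the split Bregman iteration.
#'
#' @param x numeric vector, matrix or array.
#' @param t threshold, `t >= 0`.
#' @return object of the same shape as `x`.
#' @export
soft_threshold <- function(x, t) {
  if (!is.finite(t) || t < 0) stop_invalid("threshold must be >= 0")
  sign(x) * pmax(abs(x) - t, 0)
}

#' Isotropic vector shrinkage of a gradient field
#'
#' At each pixel scales the vector `(gx, gz)` by `max(|.| - t, 0) / |.|`
#' (zero where the magnitude is zero) — the proximal operator of the
#' isotropic TV seminorm used for the TV splitting variable.
#'
#' @param g a `gradient_field`.
#' @param t threshold, `t >= 0`.
#' @return a `gradient_field`.
#' @export
vector_shrink <- function(g, t) {
  stopifnot(inherits(g, "gradient_field"))
  if (!is.finite(t) || t < 0) stop_invalid("threshold must be >= 0")
  mag <- sqrt(g$gx^2 + g$gz^2)
  fac <- ifelse(mag > 0, pmax(mag - t, 0) / mag, 0)
  structure(list(gx = g$gx * fac, gz = g$gz * fac), class = "gradient_field")
}

#' n%-compressibility ratio of a slice in a transform domain
#'
#' Transforms the slice (TV: per-pixel isotropic gradient magnitude;
#' identity: the slice itself; wavelet: the Daubechies-8 coefficient array)
#' and returns the proportion of entries with magnitude exceeding
#' `n_percent`% of the largest magnitude. Smaller ratios mean a more
#' compressible image; the ratio is invariant to global rescaling.
#'
#' @param f slice matrix (not all zeros).
#' @param n_percent relative threshold in percent, in (0, 100).
#' @param domain `"TV"`, `"identity"` or `"wavelet"`.
#' @param levels wavelet decomposition depth when `domain = "wavelet"`.
#' @return ratio in (0, 1\].
#' @export
compressibility_ratio <- function(f, n_percent = 5,
                                  domain = c("TV", "identity", "wavelet"),
                                  levels = 4) {
  domain <- match.arg(domain)
  f <- check_slice(f)
  if (all(f == 0)) stop_degenerate("all-zero slice has no compressibility ratio")
  if (!is.finite(n_percent) || n_percent <= 0 || n_percent >= 100)
    stop_invalid("n_percent must be in (0, 100)")
  v <- switch(domain,
    TV = { g <- grad2d(f); sqrt(g$gx^2 + g$gz^2) },
    identity = f,
    wavelet = as.vector(wavelet_forward(f, levels = levels)))
  v <- abs(as.vector(v))
  mx <- max(v)
  if (mx == 0) stop_degenerate("transform of input is identically zero")
  mean(v > (n_percent / 100) * mx)
}
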