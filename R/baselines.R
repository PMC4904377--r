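#' Weighted backprojection (filtered backprojection) of one slice
#'
#' Each projection row is ramp-filtered in the frequency domain (zero-padded
#' to the next power of two at least twice the detector width), optionally
#' apodized with a Hamming window, then smeared back over the slice by
#' pixel-driven linear-interpolation backprojection scaled by
#' `pi / (2 * tau)`. `filter = "none"` skips the filtering and reduces to
#' plain backprojection (strongly low-frequency weighted).
#'
#' @param y a `sinogram`.
#' @param shape slice dimensions `c(n_x, n_z)`.
#' @param filter `"ram-lak"`, `"hamming"` or `"none"`.
#' @return the reconstructed slice matrix.
#' @export
wbp_reconstruct <- function(y, shape, filter = c("ram-lak", "hamming", "none")) {
  filter <- match.arg(filter)
  stopifnot(inherits(y, "sinogram"))
  if (length(shape) != 2 || any(shape < 2))
    stop_invalid("shape must be two dimensions >= 2")
  if (ncol(y$data) != shape[1])
    stop_invalid("detector bin count must equal n_x")
  tau <- nrow(y$data); sigma <- ncol(y$data)
  if (tau < 1 || all(dim(y$data) == 0)) stop_invalid("empty sinogram")
  p <- y$data
  if (filter != "none") {
    nfft <- 2^ceiling(log2(max(64, 2 * sigma)))
    freq <- c(seq(0, nfft / 2), seq(nfft / 2 - 1, 1)) / nfft  # |omega|/(2pi)
    ramp <- 2 * freq
    if (filter == "hamming") {
      wdw <- 0.54 + 0.46 * cos(2 * pi * freq)
      ramp <- ramp * wdw
    }
    pad <- matrix(0, tau, nfft)
    pad[, seq_len(sigma)] <- p
    ft <- t(apply(pad, 1, function(row) Re(
      stats::fft(stats::fft(row) * ramp, inverse = TRUE)) / nfft))
    p <- ft[, seq_len(sigma), drop = FALSE]
  }
  bp <- cpp_backproject(p, as.integer(shape[1]), as.integer(shape[2]),
                        y$angles$angles_deg)
  bp * pi / (2 * tau)
}

#' SIRT reconstruction of one slice
#'
#' Simultaneous iterative reconstruction: starting from zero, repeats
#' `f <- f + relax * C * R^T (Rw * (y - R f))` where `Rw` holds reciprocal
#' row sums of the projector (per-measurement normalization) and `C`
#' reciprocal column sums (per-pixel normalization); zero sums are replaced
#' by zero weights rather than raising an error. Deterministic.
#'
#' @param y a `sinogram`.
#' @param shape slice dimensions `c(n_x, n_z)`.
#' @param iters iteration count, >= 1 (default 30).
#' @param relax relaxation factor in (0, 2].
#' @return the reconstructed slice matrix.
#' @export
sirt_reconstruct <- function(y, shape, iters = 30, relax = 1) {
  stopifnot(inherits(y, "sinogram"))
  if (length(shape) != 2 || any(shape < 2))
    stop_invalid("shape must be two dimensions >= 2")
  if (ncol(y$data) != shape[1])
    stop_invalid("detector bin count must equal n_x")
  if (!is.finite(iters) || iters < 1) stop_invalid("iters must be >= 1")
  if (!is.finite(relax) || relax <= 0 || relax > 2)
    stop_invalid("relax must be in (0, 2]")
  th <- y$angles$angles_deg
  nx <- as.integer(shape[1]); nz <- as.integer(shape[2])
  ones_img <- matrix(1, nx, nz)
  row_sums <- cpp_radon_forward(ones_img, th)
  Rw <- ifelse(row_sums > 0, 1 / row_sums, 0)
  ones_sino <- matrix(1, length(th), nx)
  col_sums <- cpp_radon_adjoint(ones_sino, nx, nz, th)
  Cw <- ifelse(col_sums > 0, 1 / col_sums, 0)
  f <- matrix(0, nx, nz)
  for (it in seq_len(iters)) {
    resid <- y$data - cpp_radon_forward(f, th)
    f <- f + relax * Cw * cpp_radon_adjoint(Rw * resid, nx, nz, th)
  }
  f
}
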