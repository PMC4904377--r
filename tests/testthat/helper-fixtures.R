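# Shared helpers: dense operator materialization and tiny phantoms.

# Materialize the discrete Radon operator as a dense matrix by projecting
# every standard basis image.
dense_radon_matrix <- function(nx, nz, a) {
  R <- matrix(0, length(a) * nx, nx * nz)
  for (p in seq_len(nx * nz)) {
    e <- matrix(0, nx, nz)
    e[p] <- 1
    R[, p] <- as.vector(radon_forward(e, a)$data)
  }
  R
}

# Materialize the wavelet analysis operator (fixed levels) as a dense matrix.
dense_wavelet_matrix <- function(n, levels) {
  W <- matrix(0, n * n, n * n)
  for (p in seq_len(n * n)) {
    e <- matrix(0, n, n)
    e[p] <- 1
    W[, p] <- as.vector(wavelet_forward(e, levels))
  }
  W
}

# Two high-contrast discs on a zero background (piecewise constant).
two_disc_phantom <- function(n = 32) {
  xg <- matrix(seq_len(n), n, n)
  zg <- matrix(rep(seq_len(n), each = n), n, n)
  0.8 * ((xg - 12)^2 + (zg - 14)^2 <= 36) +
    0.5 * ((xg - 22)^2 + (zg - 22)^2 <= 16)
}

# Centred smooth blob supported well inside the inscribed disc (for mass
# conservation checks of the interpolating projector).
gaussian_blob <- function(n = 64, sigma = n / 8) {
  c0 <- (n + 1) / 2
  outer(seq_len(n), seq_len(n),
        function(i, k) exp(-((i - c0)^2 + (k - c0)^2) / (2 * sigma^2)))
}

# Block-average downsampling by an integer factor.
downsample2 <- function(m, f) {
  out <- matrix(0, nrow(m) / f, ncol(m) / f)
  for (i in seq_len(f)) for (j in seq_len(f))
    out <- out + m[seq(i, nrow(m), by = f), seq(j, ncol(m), by = f)]
  out / f^2
}

# Small membrane phantom used across tests (fast to generate).
tiny_membrane <- function(seed = 1, dims = c(32, 4, 32)) {
  make_membrane_phantom(membrane_phantom_spec(
    dims = dims, n_shells = 6, n_filled = 8, semiaxis_range = c(2, 10),
    shell_thickness_range = c(1, 2), seed = seed))
}
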