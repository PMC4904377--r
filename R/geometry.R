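#' Tilt-angle sets for single-axis tomography
#'
#' An `angle_set` is an ordered vector of tilt angles in degrees about the
#' y-axis; 0 degrees points the beam along z. Angles are strictly ascending
#' and restricted to \[-90, 90\].
#'
#' @param angles_deg numeric vector of angles in degrees.
#' @param scheme one of `"uniform"`, `"undersampled"`, `"random"`.
#' @param seed integer seed used to generate the set, or `NULL`.
#' @return an object of class `angle_set`.
#' @export
angle_set <- function(angles_deg, scheme = c("uniform", "undersampled", "random"),
                      seed = NULL) {
  scheme <- match.arg(scheme)
  angles_deg <- as.numeric(angles_deg)
  if (length(angles_deg) == 0) stop_invalid("angle set must be non-empty")
  if (any(!is.finite(angles_deg))) stop_invalid("angles must be finite")
  if (any(angles_deg < -90 | angles_deg > 90))
    stop_invalid("angles must lie in [-90, 90] degrees")
  if (is.unsorted(angles_deg, strictly = TRUE) && length(angles_deg) > 1)
    stop_invalid("angles must be strictly ascending")
  structure(list(angles_deg = angles_deg, scheme = scheme, seed = seed),
            class = "angle_set")
}

#' @export
length.angle_set <- function(x) length(x$angles_deg)

#' @export
print.angle_set <- function(x, ...) {
  cat(sprintf("<angle_set> %d tilts (%s), %.2f to %.2f deg\n",
              length(x), x$scheme, min(x$angles_deg), max(x$angles_deg)))
  invisible(x)
}

#' Uniformly incremented tilt scheme
#'
#' Builds the conventional tilt series `-max_tilt, -max_tilt + inc, ...,
#' +max_tilt` (both endpoints included).
#'
#' @param max_tilt_deg half-range of the tilt series in degrees, in (0, 90].
#' @param increment_deg angular increment in degrees.
#' @return an `angle_set` with `scheme = "uniform"`.
#' @examples
#' length(make_uniform_angles(70, 2))  # 71 tilts
#' @export
make_uniform_angles <- function(max_tilt_deg, increment_deg) {
  if (!is.finite(max_tilt_deg) || max_tilt_deg <= 0 || max_tilt_deg > 90)
    stop_invalid("max_tilt_deg must be in (0, 90]")
  if (!is.finite(increment_deg) || increment_deg <= 0)
    stop_invalid("increment_deg must be positive")
  if (increment_deg > 2 * max_tilt_deg)
    stop_invalid("increment exceeds the full tilt range")
  n <- floor(2 * max_tilt_deg / increment_deg + 1e-9)
  a <- -max_tilt_deg + increment_deg * (0:n)
  # guarantee the +max_tilt endpoint when the increment divides the range
  a[abs(a - max_tilt_deg) < 1e-9] <- max_tilt_deg
  angle_set(a, "uniform")
}

#' Keep every k-th projection of a tilt series
#'
#' Retains indices 1, 1+k, 1+2k, ... (the first angle is always kept).
#'
#' @param a an `angle_set`.
#' @param k undersampling factor, a positive integer; `k = 1` returns the
#'   input unchanged.
#' @return an `angle_set` with `scheme = "undersampled"` (unless `k = 1`).
#' @export
undersample_angles <- function(a, k) {
  stopifnot(inherits(a, "angle_set"))
  if (!is.finite(k) || k < 1 || k != round(k))
    stop_invalid("k must be a positive integer")
  if (k == 1) return(a)
  idx <- seq(1, length(a), by = k)
  angle_set(a$angles_deg[idx], "undersampled", seed = a$seed)
}

#' Random tilt angles in a symmetric range
#'
#' Draws `n` i.i.d. angles uniformly on `[-max_tilt_deg, +max_tilt_deg]` and
#' sorts them ascending. Duplicates are not removed (a measure-zero event).
#'
#' @param n number of tilts.
#' @param max_tilt_deg half-range in degrees.
#' @param seed integer seed (required for reproducibility).
#' @return an `angle_set` with `scheme = "random"`.
#' @export
make_random_angles <- function(n, max_tilt_deg, seed) {
  if (!is.finite(n) || n < 1) stop_invalid("n must be >= 1")
  if (!is.finite(max_tilt_deg) || max_tilt_deg <= 0 || max_tilt_deg > 90)
    stop_invalid("max_tilt_deg must be in (0, 90]")
  a <- with_seed(seed, sort(runif(n, -max_tilt_deg, max_tilt_deg)))
  angle_set(a, "random", seed = seed)
}

#' Sinogram container
#'
#' Per-slice projection data: a `tau x sigma` matrix of line integrals, one
#' row per tilt angle, one column per detector bin (bin width = one image
#' pixel, detector centred on the rotation centre).
#'
#' @param data numeric matrix, `length(angles)` rows.
#' @param angles an `angle_set`.
#' @param detector_spacing detector bin width in image pixels.
#' @return an object of class `sinogram`.
#' @export
sinogram <- function(data, angles, detector_spacing = 1) {
  stopifnot(inherits(angles, "angle_set"))
  data <- as.matrix(data)
  if (nrow(data) != length(angles))
    stop_invalid("sinogram row count (", nrow(data),
                 ") must equal number of angles (", length(angles), ")")
  if (any(!is.finite(data))) stop_invalid("sinogram values must be finite")
  structure(list(data = data, angles = angles,
                 detector_spacing = detector_spacing),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> %d tilts x %d bins\n", nrow(x$data), ncol(x$data)))
  invisible(x)
}

check_slice <- function(f) {
  f <- as.matrix(f)
  if (nrow(f) < 2 || ncol(f) < 2) stop_invalid("slice must be at least 2x2")
  if (any(!is.finite(f))) stop_invalid("slice values must be finite")
  f
}

#' Discrete Radon transform of a slice
#'
#' Joseph-type ray-driven forward projection with linear interpolation along
#' each ray: entry (i, j) approximates the line integral of `f` along the ray
#' of detector bin j at tilt angle i. The detector has `sigma = nrow(f)` bins
#' of one-pixel width, centred on the image centre.
#'
#' @param f slice matrix (`n_x` rows = x, `n_z` columns = z).
#' @param a an `angle_set`.
#' @return a `sinogram`.
#' @export
radon_forward <- function(f, a) {
  stopifnot(inherits(a, "angle_set"))
  f <- check_slice(f)
  sinogram(cpp_radon_forward(f, a$angles_deg), a)
}

#' Adjoint of the discrete Radon transform
#'
#' The exact algebraic transpose of [radon_forward()] (same interpolation
#' weights, scattered instead of gathered), as required for the
#' conjugate-gradient normal operator: `<Rf, y> = <f, R^T y>`.
#'
#' @param s a `sinogram`.
#' @param shape target slice dimensions `c(n_x, n_z)`; `n_x` must equal the
#'   detector bin count.
#' @return a slice matrix of dimension `shape`.
#' @export
radon_adjoint <- function(s, shape) {
  stopifnot(inherits(s, "sinogram"))
  if (length(shape) != 2 || any(shape < 2))
    stop_invalid("shape must be two dimensions >= 2")
  if (ncol(s$data) != shape[1])
    stop_invalid("detector bin count (", ncol(s$data),
                 ") must equal n_x (", shape[1], ")")
  cpp_radon_adjoint(s$data, as.integer(shape[1]), as.integer(shape[2]),
                    s$angles$angles_deg)
}

#' Mutual coherence of two dictionaries
#'
#' `sqrt(N)` times the largest absolute inner product between any
#' (sub-sampled) pair of unit-norm columns of `dictA` and `dictB`. For a pair
#' of orthonormal bases the value lies in `[1, sqrt(N)]`; the Euclidean and
#' Fourier bases attain the incoherent extreme 1.
#'
#' @param dictA,dictB matrices (possibly complex) whose columns are unit-norm
#'   vectors of common dimension N.
#' @param sample_fraction fraction of columns of each dictionary to sample
#'   (1 = use all columns).
#' @param seed integer seed for the subsampling.
#' @return scalar coherence estimate.
#' @export
mutual_coherence <- function(dictA, dictB, sample_fraction = 1, seed = NULL) {
  if (nrow(dictA) != nrow(dictB))
    stop_invalid("dictionaries must share the ambient dimension")
  if (sample_fraction <= 0 || sample_fraction > 1)
    stop_invalid("sample_fraction must be in (0, 1]")
  N <- nrow(dictA)
  pick <- function(m) {
    nc <- ncol(m)
    if (sample_fraction >= 1) return(m)
    idx <- sort(sample.int(nc, max(1L, round(sample_fraction * nc))))
    m[, idx, drop = FALSE]
  }
  sub <- with_seed(seed, list(A = pick(dictA), B = pick(dictB)))
  g <- Conj(t(sub$A)) %*% sub$B
  sqrt(N) * max(Mod(g))
}

#' Compressed-sensing measurement bound
#'
#' The minimum number of random measurements `m = C * mu^2 * k * log(N)`
#' (natural logarithm) sufficient to recover a k-sparse length-N signal at
#' mutual coherence `mu` — linear in the sparsity, logarithmic in the size.
#'
#' @param mu mutual coherence.
#' @param k sparsity level (non-zero coefficient count).
#' @param N signal length, > 1.
#' @param C the constant in the bound.
#' @return required measurement count (not rounded).
#' @export
sampling_bound <- function(mu, k, N, C = 1) {
  if (!all(is.finite(c(mu, k, N, C))) || any(c(mu, k, N, C) <= 0))
    stop_invalid("all arguments must be positive")
  if (N <= 1) stop_invalid("N must exceed 1")
  C * mu^2 * k * log(N)
}
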