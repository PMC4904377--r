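#' Specification of the simulated membrane phantom
#'
#' A 3D phantom imitating heavy-metal-stained membranous compartments: on a
#' non-zero uniform background, randomly placed ellipsoidal shells (membrane
#' cross-sections) and filled ellipsoids (dense bodies) with random sizes,
#' eccentricities, orientations and contrasts, clipped to \[0, 1\].
#'
#' @param dims volume dimensions `c(n_x, n_y, n_z)` in voxels.
#' @param background background density in (0, 1).
#' @param n_shells number of ellipsoidal shells.
#' @param n_filled number of filled ellipsoids.
#' @param semiaxis_range range of ellipsoid semi-axes in voxels.
#' @param shell_thickness_range range of shell thicknesses in voxels.
#' @param contrast_range range of additive contrasts, a sub-interval of (0, 1].
#' @param seed integer seed.
#' @return a `membrane_phantom_spec` object.
#' @export
membrane_phantom_spec <- function(dims = c(256, 100, 256), background = 0.15,
                                  n_shells = 40, n_filled = 60,
                                  semiaxis_range = c(4, 60),
                                  shell_thickness_range = c(1, 3),
                                  contrast_range = c(0.2, 0.85), seed = 1) {
  if (length(dims) != 3 || any(dims < 1)) stop_invalid("dims must be 3 positive sizes")
  if (background <= 0 || background >= 1)
    stop_invalid("background must be in (0, 1)")
  rng_ok <- function(r) length(r) == 2 && r[1] > 0 && r[2] > r[1]
  if (!rng_ok(semiaxis_range) || !rng_ok(shell_thickness_range) ||
      !rng_ok(contrast_range))
    stop_invalid("ranges must be non-degenerate increasing pairs")
  structure(list(dims = dims, background = background, n_shells = n_shells,
                 n_filled = n_filled, semiaxis_range = semiaxis_range,
                 shell_thickness_range = shell_thickness_range,
                 contrast_range = contrast_range, seed = seed),
            class = "membrane_phantom_spec")
}

# Poisson sampler that falls back to the Gaussian approximation for rates
# beyond integer range (rpois returns NA above .Machine$integer.max).
rpois_safe <- function(lambda) {
  big <- lambda > 1e7
  out <- numeric(length(lambda))
  if (any(!big)) out[!big] <- rpois(sum(!big), lambda[!big])
  if (any(big)) out[big] <- round(lambda[big] +
                                    sqrt(lambda[big]) * rnorm(sum(big)))
  out
}

# uniformly random 3D rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Add one ellipsoid (shell or filled) into vol within its bounding box.
# q(x) = |D^-1 Q^T (x - c)|; filled: q <= 1; shell: 1 - t/amin < q <= 1.
add_ellipsoid <- function(vol, center, semi, rot, contrast, shell_frac = NULL) {
  d <- dim(vol)
  rmax <- max(semi)
  lo <- pmax(1, floor(center - rmax)); hi <- pmin(d, ceiling(center + rmax))
  if (any(lo > hi)) return(vol)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  g <- expand.grid(x = xs, y = ys, z = zs)
  rel <- t(t(as.matrix(g)) - center)
  loc <- rel %*% rot                       # rotate into ellipsoid frame
  q <- sqrt((loc[, 1] / semi[1])^2 + (loc[, 2] / semi[2])^2 +
            (loc[, 3] / semi[3])^2)
  inside <- if (is.null(shell_frac)) q <= 1 else (q <= 1 & q > 1 - shell_frac)
  if (!any(inside)) return(vol)
  idx <- cbind(g$x[inside], g$y[inside], g$z[inside])
  vol[idx] <- vol[idx] + contrast
  vol
}

#' Generate the membrane phantom volume
#'
#' Builds the background-filled volume described by the spec, superimposing
#' additive ellipsoidal shells and filled bodies and clipping to \[0, 1\].
#' Reproducible for a fixed `spec$seed`.
#'
#' @param spec a [membrane_phantom_spec()].
#' @return an `n_x x n_y x n_z` array with values in (0, 1\].
#' @export
make_membrane_phantom <- function(spec = membrane_phantom_spec()) {
  stopifnot(inherits(spec, "membrane_phantom_spec"))
  d <- spec$dims
  with_seed(spec$seed, {
    vol <- array(spec$background, dim = d)
    n_total <- spec$n_shells + spec$n_filled
    kinds <- rep(c("shell", "filled"), c(spec$n_shells, spec$n_filled))
    for (i in seq_len(n_total)) {
      semi <- runif(3, spec$semiaxis_range[1],
                    min(spec$semiaxis_range[2], max(d) / 2))
      center <- sapply(d, function(n) runif(1, 1, n))
      rot <- random_rotation()
      contrast <- runif(1, spec$contrast_range[1], spec$contrast_range[2])
      if (kinds[i] == "shell") {
        thick <- runif(1, spec$shell_thickness_range[1],
                       spec$shell_thickness_range[2])
        vol <- add_ellipsoid(vol, center, semi, rot, contrast,
                             shell_frac = thick / min(semi))
      } else {
        # dense bodies are smaller than membrane compartments
        vol <- add_ellipsoid(vol, center, semi / 2, rot, contrast)
      }
    }
    pmin(pmax(vol, 0), 1)
  })
}

#' Generate the nanoparticle phantom slice
#'
#' High-contrast piecewise-constant discs and crescents (a disc minus an
#' offset interior disc) on a zero background, mimicking a cross-section
#' through an assembly of inorganic nanoparticles.
#'
#' @param dims slice dimensions `c(n_x, n_z)`.
#' @param n_discs number of filled discs.
#' @param n_crescents number of crescent shapes.
#' @param seed integer seed.
#' @param contrasts the set of density values structures draw from.
#' @return a slice matrix, piecewise constant.
#' @export
make_nanoparticle_phantom <- function(dims = c(256, 256), n_discs = 12,
                                      n_crescents = 6, seed = 1,
                                      contrasts = c(0.6, 0.8, 1)) {
  if (length(dims) != 2 || any(dims < 2)) stop_invalid("dims must be 2 sizes >= 2")
  with_seed(seed, {
    f <- matrix(0, dims[1], dims[2])
    xg <- matrix(seq_len(dims[1]), dims[1], dims[2])
    zg <- matrix(rep(seq_len(dims[2]), each = dims[1]), dims[1], dims[2])
    rmax <- min(dims) / 8
    place <- function(f, crescent) {
      r <- runif(1, rmax / 4, rmax)
      cx <- runif(1, 1 + r, dims[1] - r); cz <- runif(1, 1 + r, dims[2] - r)
      val <- sample(contrasts, 1)
      disc <- (xg - cx)^2 + (zg - cz)^2 <= r^2
      f[disc] <- val
      if (crescent) {
        off <- r * 0.4 * c(cos(a <- runif(1, 0, 2 * pi)), sin(a))
        hole <- (xg - cx - off[1])^2 + (zg - cz - off[2])^2 <= (0.7 * r)^2
        f[hole] <- 0
      }
      f
    }
    for (i in seq_len(n_discs)) f <- place(f, FALSE)
    for (i in seq_len(n_crescents)) f <- place(f, TRUE)
    f
  })
}

#' Project a volume into per-slice sinograms
#'
#' Applies [radon_forward()] independently to each x-z slice (one per y
#' index), preserving slice order — the tilt-series simulation for
#' single-axis parallel-beam geometry.
#'
#' @param v an `n_x x n_y x n_z` array.
#' @param a an `angle_set`.
#' @return list of `sinogram` objects, one per y-slice.
#' @export
project_volume <- function(v, a) {
  stopifnot(is.array(v), length(dim(v)) == 3, inherits(a, "angle_set"))
  lapply(seq_len(dim(v)[2]), function(iy) radon_forward(v[, iy, ], a))
}

#' Noise specification for simulated projections
#'
#' @param poisson_rate expected counts at the mean projection value
#'   (nanoparticle mode), default 5500.
#' @param gaussian_frac Gaussian noise standard deviation as a fraction of
#'   the projection mean (nanoparticle mode), default 0.10.
#' @param target_frac target post-background noise fraction (membrane mode),
#'   default 0.10.
#' @param background_level projection-domain background used by the membrane
#'   calibration: a scalar, a matrix congruent with the sinogram, or `NULL`
#'   (taken as zero).
#' @param seed integer seed.
#' @return a `noise_spec` object.
#' @export
noise_spec <- function(poisson_rate = 5500, gaussian_frac = 0.10,
                       target_frac = 0.10, background_level = NULL, seed = 1) {
  if (!is.finite(poisson_rate) || poisson_rate <= 0)
    stop_invalid("poisson_rate must be positive")
  for (fr in c(gaussian_frac, target_frac))
    if (!is.finite(fr) || fr < 0 || fr >= 1)
      stop_invalid("noise fractions must be in [0, 1)")
  structure(list(poisson_rate = poisson_rate, gaussian_frac = gaussian_frac,
                 target_frac = target_frac, background_level = background_level,
                 seed = seed), class = "noise_spec")
}

#' Calibrate the membrane-mode Poisson scale
#'
#' Finds the count scale `s` such that rescaled Poisson sampling
#' (`Pois(s y) / s`, per-entry standard deviation `sqrt(y / s)`) has an
#' expected mean deviation equal to `target_frac` times the mean of the
#' background-subtracted projection:
#' `mean(sqrt(y / s)) = target_frac * mean(y - background)`, giving
#' `s = (mean(sqrt(y)) / (target_frac * mean(y - background)))^2`
#' (so `s` scales as `target_frac^-2`).
#'
#' @param y a `sinogram` or nonnegative matrix of clean projections.
#' @param target_frac target noise fraction.
#' @param background_level scalar or congruent matrix of projection-domain
#'   background values.
#' @return the positive Poisson scale `s`.
#' @export
calibrate_membrane_noise <- function(y, target_frac = 0.10,
                                     background_level = 0) {
  m <- if (inherits(y, "sinogram")) y$data else as.matrix(y)
  if (any(m < 0)) stop_invalid("projections must be nonnegative")
  if (!is.finite(target_frac) || target_frac <= 0)
    stop_invalid("target_frac must be positive")
  target_mean <- mean(m - background_level)
  if (!is.finite(target_mean) || target_mean <= 0)
    stop_degenerate("mean background-subtracted projection must be positive")
  (mean(sqrt(m)) / (target_frac * target_mean))^2
}

#' Apply the simulated-projection noise models
#'
#' Nanoparticle mode: the sinogram is scaled so its mean equals
#' `poisson_rate`, Poisson-sampled per entry, rescaled back, then corrupted
#' with zero-mean Gaussian noise of standard deviation
#' `gaussian_frac * mean(y)`. Membrane mode: Poisson-only noise at a scale
#' calibrated by [calibrate_membrane_noise()] so that the average noise
#' level is `target_frac` of the background-subtracted projection mean.
#' Shape and angle metadata are preserved; reproducible under `ns$seed`.
#'
#' @param y a `sinogram` with nonnegative entries.
#' @param ns a [noise_spec()].
#' @param mode `"nanoparticle"` or `"membrane"`.
#' @return a `sinogram` of noisy projections.
#' @export
add_poisson_gaussian_noise <- function(y, ns = noise_spec(),
                                       mode = c("nanoparticle", "membrane")) {
  mode <- match.arg(mode)
  stopifnot(inherits(y, "sinogram"), inherits(ns, "noise_spec"))
  m <- y$data
  if (any(m < 0)) stop_invalid("count-based noise needs nonnegative projections")
  noisy <- with_seed(ns$seed, {
    if (mode == "nanoparticle") {
      mu <- mean(m)
      if (mu == 0) {
        m
      } else {
        s <- ns$poisson_rate / mu
        out <- rpois_safe(as.vector(s * m)) / s
        out <- out + rnorm(length(m), sd = ns$gaussian_frac * mu)
        matrix(out, nrow(m), ncol(m))
      }
    } else {
      bg <- if (is.null(ns$background_level)) 0 else ns$background_level
      s <- calibrate_membrane_noise(m, ns$target_frac, bg)
      matrix(rpois_safe(as.vector(s * m)) / s, nrow(m), ncol(m))
    }
  })
  sinogram(noisy, y$angles, y$detector_spacing)
}
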