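test_that("the membrane phantom respects its specification", {
  spec <- membrane_phantom_spec(dims = c(48, 6, 48), n_shells = 8,
                                n_filled = 10, semiaxis_range = c(3, 16),
                                shell_thickness_range = c(1, 2), seed = 4)
  v <- make_membrane_phantom(spec)
  expect_equal(dim(v), c(48, 6, 48))
  expect_true(all(v >= 0 & v <= 1))
  expect_gt(min(v), 0)                      # non-zero background everywhere
  expect_gt(mean(v), spec$background)       # structures add density
  # seeded reproducibility; different seeds differ
  expect_identical(v, make_membrane_phantom(spec))
  spec2 <- spec; spec2$seed <- 5
  expect_false(identical(v, make_membrane_phantom(spec2)))
  # default geometry matches the published array size
  d <- membrane_phantom_spec()$dims
  expect_equal(d, c(256, 100, 256))
  expect_equal(prod(d), 6553600)
  expect_error(membrane_phantom_spec(background = 0),
               class = "csetr_invalid_parameter")
})

test_that("the nanoparticle phantom is piecewise constant and sparse", {
  z <- make_nanoparticle_phantom(c(64, 64), 0, 0, seed = 1)
  expect_equal(z, matrix(0, 64, 64))
  f <- make_nanoparticle_phantom(c(128, 128), n_discs = 6, n_crescents = 3,
                                 seed = 2, contrasts = c(0.6, 0.8, 1))
  expect_lte(length(unique(as.vector(f))), 4)   # background + contrasts
  expect_identical(f, make_nanoparticle_phantom(c(128, 128), 6, 3, seed = 2,
                                                contrasts = c(0.6, 0.8, 1)))
  # the nanoparticle slice is sparser than a membrane slice of comparable
  # structural density in the identity domain (membrane background
  # subtracted first, as in the experimental-sparsity protocol)
  mem <- make_membrane_phantom(membrane_phantom_spec(
    dims = c(128, 2, 128), n_shells = 20, n_filled = 30,
    semiaxis_range = c(2, 30), shell_thickness_range = c(1, 2), seed = 6))
  r_np <- compressibility_ratio(f, 5, "identity")
  r_mem <- compressibility_ratio(mem[, 1, ] - 0.15, 5, "identity")
  expect_lt(r_np, r_mem)
})

test_that("sparsity ordering: nanoparticle < membrane < pure noise", {
  set.seed(30)
  np <- make_nanoparticle_phantom(c(64, 64), 3, 1, seed = 3)
  mem <- tiny_membrane(seed = 7, dims = c(64, 4, 64))
  noise <- matrix(rnorm(64 * 64), 64, 64)
  for (dm in c("TV", "identity", "wavelet")) {
    r_np <- compressibility_ratio(np, 5, dm)
    r_mem <- mean(sapply(1:4, function(i)
      compressibility_ratio(mem[, i, ] - if (dm == "identity") 0.15 else 0,
                            5, dm)))
    r_noise <- compressibility_ratio(noise, 5, dm)
    expect_lt(r_np, r_mem)
    expect_lt(r_mem, r_noise)
  }
})

test_that("volume projection is slice-wise and mass-conserving", {
  a <- make_uniform_angles(70, 10)
  zv <- array(0, dim = c(16, 3, 16))
  sz <- project_volume(zv, a)
  expect_length(sz, 3)
  expect_true(all(vapply(sz, function(s) all(s$data == 0), logical(1))))

  v1 <- array(gaussian_blob(32), dim = c(32, 1, 32))
  s1 <- project_volume(v1, a)
  expect_equal(s1[[1]]$data, radon_forward(v1[, 1, ], a)$data)
  # per-row mass conservation for the interior-supported smooth slice
  expect_equal(rowSums(s1[[1]]$data) / sum(v1), rep(1, length(a)),
               tolerance = 1e-4)
})

test_that("nanoparticle-mode noise matches its closed-form variance", {
  a <- make_uniform_angles(70, 2)
  blob <- 50 * gaussian_blob(128, 20)
  y <- radon_forward(blob, a)
  # zero sinogram passes through unchanged
  z <- sinogram(matrix(0, length(a), 128), a)
  expect_equal(add_poisson_gaussian_noise(z, noise_spec(seed = 1),
                                          "nanoparticle")$data, z$data)
  # infinite-dose limit: at rate 1e9 the output converges to the input
  hi <- add_poisson_gaussian_noise(y, noise_spec(poisson_rate = 1e9,
                                                 gaussian_frac = 0, seed = 2),
                                   "nanoparticle")
  expect_lt(max(abs(hi$data - y$data)), 0.001 * mean(y$data))
  # Monte-Carlo check of Poisson(5500) + 10% Gaussian at the mean:
  # var = mean(y) * y / 5500 + (0.1 * mean(y))^2 averaged over entries
  ns <- noise_spec(seed = 3)
  noisy <- add_poisson_gaussian_noise(y, ns, "nanoparticle")
  dev <- noisy$data - y$data
  var_i <- mean(y$data) * y$data / 5500 + (0.1 * mean(y$data))^2
  pred_var <- mean(var_i)
  se <- sqrt(2 * mean(var_i^2) / length(dev))  # s.e. of the variance estimate
  expect_lt(abs(mean(dev^2) - pred_var), 3 * se)
  # negative projections are rejected
  neg <- sinogram(matrix(-1, length(a), 128), a)
  expect_error(add_poisson_gaussian_noise(neg, ns, "nanoparticle"),
               class = "csetr_invalid_parameter")
})

test_that("membrane-mode noise calibration hits its closed form and target", {
  a <- make_uniform_angles(70, 2)
  # constant sinogram: s = 1 / (target^2 * c)
  cst <- sinogram(matrix(40, length(a), 64), a)
  s <- calibrate_membrane_noise(cst, target_frac = 0.1, background_level = 0)
  expect_equal(s, 1 / (0.1^2 * 40), tolerance = 1e-12)
  # quartering under target doubling
  expect_equal(calibrate_membrane_noise(cst, 0.2, 0), s / 4, tolerance = 1e-12)
  # Monte-Carlo closure: attained noise fraction within 10% relative
  blob <- 30 * gaussian_blob(128, 24) + 10
  y <- radon_forward(blob, a)
  bg <- radon_forward(matrix(10, 128, 128), a)$data
  ns <- noise_spec(target_frac = 0.1, background_level = bg, seed = 4)
  noisy <- add_poisson_gaussian_noise(y, ns, "membrane")
  attained <- sd(noisy$data - y$data) / mean(y$data - bg)
  expect_lt(abs(attained - 0.1) / 0.1, 0.1)
  # shape and metadata preserved
  expect_equal(dim(noisy$data), dim(y$data))
  expect_identical(noisy$angles, y$angles)
  expect_error(calibrate_membrane_noise(cst, 0.1, background_level = 40),
               class = "csetr_degenerate_input")
})
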