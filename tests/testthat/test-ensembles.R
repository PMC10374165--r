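test_that("quartic SNR calibration has the right closed-form endpoints and midpoint", {
  expect_equal(gamma_of_mu(0), 16 / 27, tolerance = 1e-12)
  expect_equal(gamma_of_mu(1), 0, tolerance = 1e-12)
  ## midpoint cross-checked against the equilibrium-measure solve
  expect_equal(gamma_of_mu(0.5), 0.276032, tolerance = 1e-5)
  expect_error(gamma_of_mu(1.2), "0, 1")
  expect_error(gamma_of_mu(-0.1), "0, 1")
})

test_that("support half-width matches the density normalization", {
  expect_equal(a_squared(0, 16 / 27), 3 / 4, tolerance = 1e-12)
  expect_equal(a_squared(1, 0), 1, tolerance = 1e-12)
  expect_equal(a_squared(0.5, gamma_of_mu(0.5)), 0.83772, tolerance = 1e-4)
  expect_error(a_squared(0, 0), "degenerate")
})

test_that("limiting density is a calibrated probability density across the family", {
  for (mu in c(0, 0.25, 0.5, 0.75, 1)) {
    sp <- ensemble_spec("quartic", mu)
    expect_equal(spectral_moment(sp, 0), 1, tolerance = 1e-8)
    expect_equal(spectral_moment(sp, 2), 1, tolerance = 1e-6)
  }
  sp0 <- ensemble_spec("quartic", 0)
  a <- sqrt(sp0$a_sq)
  expect_equal(rho_density(c(-2 * a, 2 * a), sp0), c(0, 0))
  expect_equal(rho_density(0, sp0), (8 / 9) * sqrt(3) / (2 * pi),
               tolerance = 1e-10)
  xs <- seq(0.1, 1.5, by = 0.2)
  expect_equal(rho_density(xs, sp0), rho_density(-xs, sp0))
  expect_equal(rho_density(10, sp0), 0)
})

test_that("goe family is the unit-variance semicircle", {
  g <- ensemble_spec("goe")
  expect_equal(g$mu, 1)
  expect_equal(g$gamma, 0)
  expect_equal(g$a_sq, 1)
  expect_equal(rho_density(0, g), 1 / pi, tolerance = 1e-12)
  ## quartic at mu = 1 collapses onto the goe spec
  q1 <- ensemble_spec("quartic", 1)
  expect_equal(q1$family, "goe")
})

test_that("signal priors respect their normalization conventions", {
  n <- 5000
  x <- sample_signal(prior_spec("rademacher"), n, seed = 1)
  expect_true(all(x %in% c(-1, 1)))
  x <- sample_signal(prior_spec("spherical"), n, seed = 1)
  expect_equal(sum(x^2), n, tolerance = 1e-10)
  pr <- prior_spec("sparse_rademacher", sparsity = 0.25)
  x <- sample_signal(pr, n, seed = 2)
  expect_true(all(x %in% c(-2, 0, 2)))
  expect_equal(mean(x^2), 1, tolerance = 5 * sqrt(3 / n))
  expect_error(prior_spec("sparse_rademacher", sparsity = 0),
               "sparsity")
  ## determinism
  expect_identical(sample_signal(pr, 50, seed = 7),
                   sample_signal(pr, 50, seed = 7))
})

test_that("noise sampler reproduces the limiting spectrum", {
  sp <- ensemble_spec("quartic", 0)
  Z <- sample_noise(800, sp, seed = 3)
  expect_identical(Z, t(Z))
  expect_identical(Z, sample_noise(800, sp, seed = 3))
  ev <- eigen(Z, symmetric = TRUE, only.values = TRUE)$values
  a <- sqrt(sp$a_sq)
  expect_true(all(abs(ev) <= 2 * a + 1e-8))
  ## KS against the limiting CDF
  xs <- seq(-2 * a, 2 * a, length.out = 4001)
  dens <- rho_density(xs, sp)
  cdf <- cumsum((dens[-1] + dens[-length(dens)]) / 2 * diff(xs))
  Fhat <- stats::approxfun(xs, c(0, cdf / cdf[length(cdf)]), rule = 2)
  ks <- suppressWarnings(stats::ks.test(ev, Fhat))
  expect_gt(ks$p.value, 0.01)
  ## empirical fourth moment near 27/16
  expect_equal(mean(ev^4), 27 / 16, tolerance = 0.06)
})

test_that("goe sampler matches a direct Wigner matrix spectrally", {
  g <- ensemble_spec("goe")
  Z <- sample_noise(1200, g, seed = 5)
  expect_identical(Z, t(Z))
  ## off-diagonal entry variance 1/n
  od <- Z[upper.tri(Z)]
  expect_equal(stats::var(od), 1 / 1200, tolerance = 0.05)
  ev <- eigen(Z, symmetric = TRUE, only.values = TRUE)$values
  ## semicircle CDF
  Fsc <- function(x) (x * sqrt(pmax(4 - x^2, 0)) / 2 + 2 * asin(pmin(pmax(x / 2, -1), 1)) + pi) / (2 * pi)
  ks <- suppressWarnings(stats::ks.test(ev, Fsc))
  expect_gt(ks$p.value, 0.001)
  expect_equal(mean(ev^2), 1, tolerance = 0.05)
})

test_that("rotational invariance: quadratic forms are direction-independent", {
  sp <- ensemble_spec("quartic", 0)
  Z <- sample_noise(500, sp, seed = 11)
  set.seed(1)
  qf <- replicate(6, {
    u <- stats::rnorm(500); u <- u / sqrt(sum(u^2))
    sum(u * (Z %*% u))
  })
  ## each u'Zu has mean 0, var ~ 2/n sum lambda^2 / n ~ 2/n
  expect_true(all(abs(qf) < 5 * sqrt(2 / 500)))
})

test_that("hadamard eigenbasis is orthogonal with sign structure", {
  O <- hadamard_eigenbasis(64, seed = 2)
  expect_lt(max(abs(crossprod(O) - diag(64))), 1e-10)
  expect_true(all(abs(abs(O) - 1 / 8) < 1e-12))
  O2 <- hadamard_eigenbasis(2, seed = 9)
  expect_equal(abs(O2), matrix(1 / sqrt(2), 2, 2))
  expect_equal(O2[1, ], O2[2, ] * c(1, -1))
  expect_error(hadamard_eigenbasis(100, seed = 1), "power of 2")
})

test_that("assembled data follows the rank-one-plus-noise model", {
  sp <- ensemble_spec("quartic", 0)
  pr <- prior_spec("rademacher")
  x <- sample_signal(pr, 300, seed = 4)
  Z <- sample_noise(300, sp, seed = 4)
  ds <- assemble_data(x, Z, snr = 4)
  expect_identical(ds$data, t(ds$data))
  expect_equal(ds$data, sqrt(4) / 300 * tcrossprod(x) + Z)
  expect_equal(assemble_data(x, Z, snr = 0)$data, Z)
  expect_error(assemble_data(x, Z, snr = -1), "nonnegative")
  expect_error(assemble_data(x, Z[1:10, 1:10], 1), "mismatch")
  ## spike eigenvalue of the rank-one part
  expect_equal(sqrt(4) * sum(x^2) / 300, 2, tolerance = 1e-12)
})

test_that("top eigenvalue of Y sits near the BBP outlier", {
  sp <- ensemble_spec("quartic", 0)
  ds <- spiked_dataset(1500, snr = 25, sp, prior_spec("rademacher"), seed = 8)
  th <- bbp_theory(sp, 25)
  ev_top <- structpca:::top_eigenvector(ds$data)$value
  expect_equal(ev_top, th$outlier, tolerance = 0.05)
})
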