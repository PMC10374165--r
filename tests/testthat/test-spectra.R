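test_that("spectral moments match closed forms", {
  g <- ensemble_spec("goe")
  expect_equal(spectral_moment(g, 4), 2, tolerance = 1e-9)     # Catalan C2
  expect_equal(spectral_moment(g, 6), 5, tolerance = 1e-9)     # Catalan C3
  sp <- ensemble_spec("quartic", 0)
  expect_equal(spectral_moment(sp, 4), 27 / 16, tolerance = 1e-9)
  expect_equal(spectral_moment(sp, 6), 27 / 8, tolerance = 1e-9)
  expect_equal(spectral_moment(sp, 3), 0)
  ## quadrature agrees with the Catalan closed form to high order
  mc <- structpca:::spectral_moments_closed(sp, 12)
  for (k in seq(0, 12, by = 2)) {
    expect_equal(spectral_moment(sp, k), mc[k + 1], tolerance = 1e-8)
  }
})

test_that("free cumulant recursion inverts the moment map", {
  ## unit semicircle: free Gaussian
  kap <- free_cumulants_from_moments(c(1, 0, 1, 0, 2, 0, 5))
  expect_equal(kap, c(0, 1, 0, 0, 0, 0), tolerance = 1e-12)
  ## quartic mu=0 closed-form low orders
  sp <- ensemble_spec("quartic", 0)
  m <- structpca:::spectral_moments_closed(sp, 12)
  kr <- free_cumulants_from_moments(m)
  expect_equal(kr[2], 1, tolerance = 1e-10)
  expect_equal(kr[4], -5 / 16, tolerance = 1e-10)
  expect_equal(kr[6], 1 / 4, tolerance = 1e-10)
  ## round trip to 1e-8 at orders <= 12
  expect_equal(moments_from_cumulants(kr), m, tolerance = 1e-8)
  expect_error(free_cumulants_from_moments(c(2, 0, 1)), "m_0")
})

test_that("non-crossing recursion equals brute-force partition enumeration", {
  ## enumeration sanity: non-crossing partition counts are Catalan numbers
  expect_equal(length(nc_partitions(4)), 14)
  expect_equal(length(nc_partitions(5)), 42)
  for (fam in list(ensemble_spec("goe"), ensemble_spec("quartic", 0),
                   ensemble_spec("quartic", 0.5), ensemble_spec("sextic"))) {
    m <- structpca:::spectral_moments_closed(fam, 8)
    kap <- free_cumulants_from_moments(m)
    m_enum <- moments_by_enumeration(kap, 8)
    expect_equal(m_enum, m[-1], tolerance = 1e-9)
  }
})

test_that("deep cumulants from the R-transform agree with the recursion where both are accurate", {
  for (fam in list(ensemble_spec("quartic", 0), ensemble_spec("quartic", 0.5),
                   ensemble_spec("sextic"))) {
    kf <- free_cumulants(fam, 14)
    kr <- free_cumulants_from_moments(structpca:::spectral_moments_closed(fam, 14))
    expect_equal(kf, kr, tolerance = 1e-8)
    expect_equal(kf[2], 1, tolerance = 1e-9)
    expect_equal(kf[seq(1, 13, by = 2)], rep(0, 7))
  }
})

test_that("stieltjes transform matches the semicircle closed form and 1/z tail", {
  g <- ensemble_spec("goe")
  for (z in c(2.5, 3, 5)) {
    expect_equal(stieltjes_transform(g, z), (z - sqrt(z^2 - 4)) / 2,
                 tolerance = 1e-8)
  }
  sp <- ensemble_spec("quartic", 0)
  expect_equal(stieltjes_transform(sp, 1e6), 1e-6, tolerance = 1e-9)
  ## closed-form path agrees with quadrature
  for (z in c(1.75, 2, 3, -2.5)) {
    expect_equal(stieltjes_transform(sp, z),
                 structpca:::stieltjes_closed(sp, z), tolerance = 1e-8)
  }
  ## finite at the soft edge, strictly decreasing outside
  a <- sqrt(sp$a_sq)
  ge <- structpca:::stieltjes_closed(sp, 2 * a)
  expect_true(is.finite(ge) && ge > 0)
  zs <- seq(2 * a + 0.01, 6, length.out = 40)
  expect_true(all(diff(stieltjes_transform(sp, zs)) < 0))
  expect_error(stieltjes_transform(sp, 0.5), "support")
})

test_that("BBP theory reproduces spiked-Wigner closed forms", {
  g <- ensemble_spec("goe")
  th <- bbp_theory(g, 4)
  expect_equal(th$outlier, 2.5, tolerance = 1e-9)
  expect_equal(th$overlap_sq, 0.75, tolerance = 1e-9)
  expect_equal(th$snr_threshold, 1, tolerance = 1e-9)
  th0 <- bbp_theory(g, 0.5)
  expect_false(th0$above_threshold)
  expect_equal(th0$overlap_sq, 0)
  expect_equal(th0$outlier, 2)
})

test_that("overlap is monotone in the SNR and bounded in [0,1]", {
  sp <- ensemble_spec("quartic", 0)
  lams <- seq(0.2, 12, length.out = 25)
  eps2 <- vapply(lams, function(l) bbp_theory(sp, l)$overlap_sq, numeric(1))
  expect_true(all(eps2 >= 0 & eps2 <= 1))
  expect_true(all(diff(eps2) >= -1e-12))
})

test_that("empirical top-eigenvector overlap matches the BBP prediction", {
  sp <- ensemble_spec("quartic", 0)
  th <- bbp_theory(sp, 25)
  ovl <- vapply(1:4, function(s) {
    ds <- spiked_dataset(1200, 25, sp, prior_spec("rademacher"), seed = 100 + s)
    nu <- structpca:::top_eigenvector(ds$data)$vector
    sum(nu * ds$signal)^2 / 1200
  }, numeric(1))
  se <- stats::sd(ovl) / 2
  expect_lt(abs(mean(ovl) - th$overlap_sq), max(3 * se, 0.02))
})

test_that("one-cut calibration machinery recovers the printed couplings", {
  expect_equal(sextic_xi(), 27 / 80, tolerance = 1e-8)
  expect_equal(structpca:::calibrate_quartic_gamma(0), 16 / 27, tolerance = 1e-8)
  expect_equal(structpca:::calibrate_quartic_gamma(1), 0, tolerance = 1e-8)
  expect_equal(structpca:::calibrate_quadratic(), 1, tolerance = 1e-8)
  sx <- ensemble_spec("sextic")
  expect_equal(sx$a_sq, 2 / 3, tolerance = 1e-10)
  expect_equal(spectral_moment(sx, 2), 1, tolerance = 1e-8)
  ## one-cut density nonnegative on support
  xs <- seq(-2 * sqrt(sx$a_sq), 2 * sqrt(sx$a_sq), length.out = 201)
  expect_true(all(rho_density(xs, sx) >= 0))
})

test_that("rescaled spectral estimator behaves at and below threshold", {
  g <- ensemble_spec("goe")
  ds <- spiked_dataset(400, 0, g, prior_spec("rademacher"), seed = 1)
  expect_warning(pe <- spectral_pca_estimate(ds, g), "threshold")
  expect_equal(pe$C, 0)
  expect_equal(pe$mse, 0.5, tolerance = 1e-10)
  ## sign invariance of the rank-one estimate
  ds2 <- spiked_dataset(400, 4, g, prior_spec("rademacher"), seed = 2)
  pe2 <- spectral_pca_estimate(ds2, g)
  s2 <- sum(ds2$signal^2); sv <- sum(ds2$signal * (-pe2$nu))
  mse_flip <- (s2^2 - 2 * pe2$C * sv^2 + pe2$C^2) / (2 * 400^2)
  expect_equal(mse_flip, pe2$mse, tolerance = 1e-12)
})

test_that("rescaled-PCA matrix MSE approaches (1 - eps^4)/2", {
  g <- ensemble_spec("goe")
  mses <- vapply(1:6, function(s) {
    ds <- spiked_dataset(1500, 4, g, prior_spec("rademacher"), seed = 200 + s)
    spectral_pca_estimate(ds, g)$mse
  }, numeric(1))
  target <- (1 - 0.75^2) / 2
  se <- stats::sd(mses) / sqrt(6)
  expect_lt(abs(mean(mses) - target), max(3 * se, 0.01))
})
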