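test_that("posterior-mean denoiser reproduces conjugate closed forms", {
  pr <- prior_spec("rademacher")
  g <- posterior_mean_denoiser(pr, 1, 1)
  expect_equal(g(0), 0)
  expect_equal(g(1), tanh(1), tolerance = 1e-12)
  expect_equal(g(c(-2, 0.5)), tanh(c(-2, 0.5)), tolerance = 1e-12)
  ## general channel: tanh(mu f / sigma^2)
  g2 <- posterior_mean_denoiser(pr, 2, 3)
  fs <- seq(-3, 3, by = 0.5)
  expect_equal(g2(fs), tanh(2 * fs / 3), tolerance = 1e-12)
})

test_that("sparse-Rademacher denoiser matches a quadrature Bayes oracle", {
  pr <- prior_spec("sparse_rademacher", sparsity = 0.5)
  mu <- 1.3; s2 <- 0.8
  g <- posterior_mean_denoiser(pr, mu, s2)
  ## oracle: direct Bayes rule by numerical normalization over the atoms
  oracle <- function(f) {
    w <- pr$probs * exp(-(f - mu * pr$atoms)^2 / (2 * s2))
    sum(pr$atoms * w) / sum(w)
  }
  fs <- seq(-4, 4, by = 0.25)
  expect_equal(g(fs), vapply(fs, oracle, numeric(1)), tolerance = 1e-8)
})

test_that("full-memory denoiser depends on f only through the whitened projection", {
  pr <- prior_spec("rademacher")
  mu <- c(0.5, 1.2); Sg <- matrix(c(1, 0.3, 0.3, 2), 2)
  g <- posterior_mean_denoiser(pr, mu, Sg)
  alpha <- solve(Sg, mu)
  f1 <- c(1, 0.5); f2 <- f1 + c(-alpha[2], alpha[1]) * 10  # same projection
  expect_equal(sum(alpha * f1), sum(alpha * f2), tolerance = 1e-10)
  expect_equal(g(rbind(f1)), g(rbind(f2)), tolerance = 1e-10)
  ## Gaussian prior: linear shrinkage
  gg <- posterior_mean_denoiser(prior_spec("gaussian"), 1, 1)
  expect_equal(gg(2), 1, tolerance = 1e-12)
})

test_that("state evolution is trivial without signal", {
  sp <- ensemble_spec("quartic", 0)
  se <- bamp_state_evolution(sp, j_coefficients(sp, 0), prior_spec("rademacher"),
                             snr = 0, T_max = 5)
  expect_equal(se$mse, rep(0.5, se$T), tolerance = 1e-12)
  expect_equal(se$overlap[-1], rep(0, se$T), tolerance = 1e-12)
})

test_that("GOE reduction: BAMP SE collapses to the scalar spiked-Wigner recursion", {
  g <- ensemble_spec("goe")
  se <- bamp_state_evolution(g, j_coefficients(g, 2), prior_spec("rademacher"),
                             snr = 2, T_max = 80, tol = 1e-12)
  m_or <- wigner_se_oracle(2)
  expect_equal(se$mse[se$final_t], (1 - m_or^2) / 2, tolerance = 1e-7)
  expect_equal(se$overlap[se$final_t + 1], m_or, tolerance = 1e-7)
})

test_that("Bayes-optimality structure holds along the SE trajectory", {
  se <- fx_bamp_se5()
  ## Nishimori: E[U^2] = E[X U] for posterior-mean denoisers
  expect_equal(se$q[-1], se$overlap[-1], tolerance = 1e-5)
  ## MSE consistent with the overlap under the Frobenius normalization
  expect_equal(se$mse, (1 - se$overlap[-1]^2) / 2, tolerance = 1e-5)
  ## covariance PSD at the final iteration (relative scale; rows become
  ## collinear at convergence)
  ev <- eigen(se$Sigma, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-5 * max(abs(ev))))
  ## monotone improvement once past the first iterations
  expect_true(all(diff(se$mse[2:se$T]) < 1e-7))
})

test_that("BAMP run without signal stays at MSE 1/2", {
  sp <- ensemble_spec("quartic", 0)
  ds <- spiked_dataset(400, 0, sp, prior_spec("rademacher"), seed = 31)
  run <- bamp_run(ds, prior = prior_spec("rademacher"), spec = sp,
                  T_max = 4, seed = 31)
  expect_equal(run$empirical_mse, rep(0.5, run$iterations), tolerance = 1e-10)
})

test_that("empirical BAMP tracks its state evolution at moderate size", {
  se <- fx_bamp_se5()
  ds <- fx_phase_datasets(nseeds = 1, n = 2000)[[1]]
  run <- bamp_run(ds, prior = fx_rademacher(), spec = fx_quartic0(),
                  seed = 1001, se = se)
  tt <- min(run$iterations, se$T)
  expect_lt(max(abs(run$empirical_mse[1:tt] - se$mse[1:tt])), 0.05)
  expect_true(run$converged)
})

test_that("auxiliary AMP satisfies the power-matching condition", {
  ## fixed eight-stage horizon (errors accumulate along the unrolled chain)
  se <- bamp_state_evolution(fx_quartic0(), j_coefficients(fx_quartic0(), 5),
                             fx_rademacher(), 5, T_max = 8, tol = 0)
  ds <- fx_phase_datasets(nseeds = 1, n = 2000)[[1]]
  aux <- auxiliary_amp(ds, se, seed = 1)
  expect_lt(aux$max_matching, 1e-2)
  ## stage map bookkeeping
  expect_equal(aux$stage_map$s, seq_len(nrow(aux$stage_map)))
  expect_true(all(aux$stage_map$l %in% 1:3))
  ## the Onsager table consumed by the run is the same object
  expect_identical(aux$onsager_aux, se$bbar)
})

test_that("auxiliary AMP degenerates to the main recursion when K = 1", {
  g <- ensemble_spec("goe")
  pr <- prior_spec("rademacher")
  ds <- spiked_dataset(500, 4, g, pr, seed = 41)
  se <- bamp_state_evolution(g, j_coefficients(g, 4), pr, 4, T_max = 6)
  run <- bamp_run(ds, prior = pr, spec = g, seed = 41, se = se)
  aux <- auxiliary_amp(ds, se, seed = 41)
  ## staging is degenerate: each auxiliary iterate IS the main iterate
  expect_equal(max(aux$matching), 0, tolerance = 1e-12)
  ## trajectories agree up to the O(n^{-1/2}) difference between the
  ## deterministic and empirical signal overlaps used in the splitting
  tt <- min(run$iterations, 6)
  expect_lt(max(abs(aux$iterates_u[, 1:tt] - run$iterates_u[, 1:tt])), 0.1)
})

test_that("gaussianity diagnostic accepts the null and rejects broken Onsagers", {
  se <- fx_bamp_se5()
  ds <- spiked_dataset(2000, 5, fx_quartic0(), fx_rademacher(), seed = 55)
  ## null case: residuals built exactly as mu_t X + Gaussian(Sigma_tt)
  set.seed(1)
  fake <- list(iterates_f = sapply(1:4, function(t)
    se$mu[t] * ds$signal + sqrt(se$Sigma[t, t]) * stats::rnorm(2000)),
    se = se)
  gd0 <- gaussianity_diagnostic(fake, ds$signal, se)
  expect_true(all(abs(as.matrix(gd0[, -1])) < 4))
  ## real run with the correct Onsagers
  run <- bamp_run(ds, prior = fx_rademacher(), spec = fx_quartic0(),
                  seed = 55, se = se)
  gd <- gaussianity_diagnostic(run, ds$signal)
  expect_true(all(abs(as.matrix(gd[1:5, -1])) < 6))
  ## negative control: zero out the Onsager corrections
  se_bad <- se
  se_bad$onsager <- se$onsager * 0
  run_bad <- structpca:::amp_run_engine(ds, se_bad, seed = 55)
  gd_bad <- gaussianity_diagnostic(run_bad, ds$signal, se)
  tt <- min(5, nrow(gd_bad))
  expect_gt(max(abs(as.matrix(gd_bad[1:tt, -1])), na.rm = TRUE), 6)
})
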