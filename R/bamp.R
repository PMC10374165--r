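## Bayes-optimal AMP: state evolution, the empirical algorithm, the
## auxiliary AMP diagnostic and the Gaussianity check.

#' Posterior-mean denoiser for the effective Gaussian channel
#'
#' Builds \eqn{g(f) = E[X^* \mid F = f]} under the state-evolution channel
#' \eqn{F = \mu X^* + W}, \eqn{W \sim N(0, \Sigma)}, for a separable prior.
#' With one iterate and a Rademacher prior this is
#' \eqn{\tanh(\mu f/\sigma^2)}; with several iterates the conditional mean
#' depends on \eqn{f} only through \eqn{\mu^T \Sigma^{-1} f}.
#'
#' @param prior A [prior_spec()] (\code{rademacher}, \code{sparse_rademacher}
#'   or \code{gaussian}).
#' @param mu_vec Signal loadings \eqn{\mu} (length \eqn{t}).
#' @param sigma_mat Noise covariance \eqn{\Sigma} (\eqn{t \times t} matrix,
#'   or a scalar variance when \eqn{t = 1}).
#' @return A function mapping an \eqn{n \times t} matrix (or length-\eqn{t}
#'   vector, or plain vector when \eqn{t = 1}) of iterates to the
#'   componentwise posterior mean.
#' @examples
#' g <- posterior_mean_denoiser(prior_spec("rademacher"), 1, 1)
#' g(1)    # tanh(1)
#' @export
posterior_mean_denoiser <- function(prior, mu_vec, sigma_mat) {
  stopifnot(inherits(prior, "prior_spec"))
  t <- length(mu_vec)
  Sb <- if (is.matrix(sigma_mat)) sigma_mat else matrix(sigma_mat, t, t)
  stopifnot(nrow(Sb) == t)
  es <- eigen((Sb + t(Sb)) / 2, symmetric = TRUE)
  keep <- es$values > 1e-10 * max(es$values, 0)
  if (!all(keep))
    warning("near-singular channel covariance; redundant directions dropped")
  Vk <- es$vectors[, keep, drop = FALSE]
  alpha <- as.numeric(Vk %*% (crossprod(Vk, mu_vec) / es$values[keep]))
  theta <- sum(alpha * mu_vec)
  ch <- make_channel(prior, theta, max(theta, 0), "posterior")
  function(f) {
    fm <- if (is.matrix(f)) f else matrix(f, ncol = t)
    ch$h(as.numeric(fm %*% alpha))
  }
}

#' State evolution of BAMP
#'
#' Runs the multistage state evolution: each main iteration is unrolled
#' into \eqn{K} auxiliary AMP steps on the noise matrix, whose
#' rotationally-invariant state evolution (free-cumulant Onsager rows,
#' Gaussian noise covariance) tracks the powers \eqn{Y^k u^t}; reading off
#' the expansion of \eqn{J(Y)u^t} yields the Onsager coefficients
#' \eqn{c_{t,i}}, the signal strengths \eqn{\mu_t} and the noise covariance
#' \eqn{\Sigma_t}, hence the predicted overlap and matrix MSE per
#' iteration.
#'
#' @param spec An [ensemble_spec()].
#' @param poly A \code{"preprocess_poly"} (typically [j_coefficients()]).
#' @param prior A [prior_spec()].
#' @param snr \eqn{\lambda \ge 0}.
#' @param T_max Maximum number of main iterations.
#' @param eps_init Initialization overlap \eqn{\epsilon > 0}.
#' @param tol Fixed-point tolerance on successive MSE values.
#' @return Object of class \code{"se_state"}: per-iteration \code{mu},
#'   \code{Sigma}, \code{onsager} (lower-triangular \eqn{c_{t,i}}),
#'   \code{overlap} (\eqn{m_t}), \code{mse}, plus the auxiliary bookkeeping
#'   (\code{bbar}, \code{S}, \code{gamma_tab}) and \code{converged}.
#' @export
bamp_state_evolution <- function(spec, poly, prior, snr, T_max = 30,
                                 eps_init = 0.8, tol = 1e-7, ...) {
  stopifnot(inherits(spec, "ensemble_spec"), inherits(poly, "preprocess_poly"))
  cvec <- trim_poly(poly$coefficients)
  K <- length(cvec)
  kappa <- free_cumulants(spec, 2 * K * T_max + 2)
  out <- se_engine(kappa, cvec, prior, snr, T_max, eps_init,
                   schedule = rep("single", T_max), tol = tol, ...)
  out$spec_family <- spec$family
  out$algorithm <- "bamp"
  class(out) <- "se_state"
  out
}

#' @export
print.se_state <- function(x, ...) {
  cat(sprintf("<se_state> %s  K=%d  lambda=%.4g  T=%d  converged=%s\n",
              x$algorithm, x$K, x$lambda, x$T, x$converged))
  cat(sprintf("  final overlap m=%.6f  MSE=%.6f\n",
              x$overlap[x$final_t + 1], x$mse[x$final_t]))
  invisible(x)
}

## shared empirical iteration for BAMP and the baselines
amp_run_engine <- function(dataset, se, seed, algorithm = "bamp",
                           tol = 1e-7) {
  Y <- dataset$data
  X <- dataset$signal
  n <- dataset$n
  Tse <- se$T
  eps <- se$eps
  set.seed(derive_seed(seed, "init"))
  u <- eps * X + sqrt(1 - eps^2) * stats::rnorm(n)
  U <- matrix(0, n, Tse + 1); U[, 1] <- u
  Fm <- matrix(0, n, Tse)
  ov <- numeric(Tse + 1); qq <- numeric(Tse + 1); ms <- rep(NA_real_, Tse)
  ov[1] <- sum(u * X) / n; qq[1] <- sum(u^2) / n
  poly <- list(coefficients = se$cvec)
  diverged <- FALSE
  t_done <- 0L
  for (t in seq_len(Tse)) {
    ju <- apply_poly_matvec(Y, poly, U[, t])
    f <- ju - as.numeric(U[, 1:t, drop = FALSE] %*% se$onsager[t, 1:t])
    Fm[, t] <- f
    varsig <- as.numeric(Fm[, 1:t, drop = FALSE] %*% se$alphas[[t]])
    unew <- se$channels[[t]]$h(varsig)
    U[, t + 1] <- unew
    ov[t + 1] <- sum(unew * X) / n
    qq[t + 1] <- sum(unew^2) / n
    sx2 <- sum(X^2) / n
    t_done <- t
    if (!all(is.finite(unew))) { diverged <- TRUE; break }
    if (se$schedule[t] == "identity") {
      ## identity steps collect powers of Y; their iterate is unnormalized
      ## and carries no estimate, so no MSE and no divergence call here
      ms[t] <- NA_real_
      next
    }
    ms[t] <- (sx2^2 - 2 * ov[t + 1]^2 + qq[t + 1]^2) / 2
    if (!is.finite(ms[t]) || ms[t] > 1) { diverged <- TRUE; break }
    if (t >= 2) {
      prev <- rev(which(se$schedule[1:(t - 1)] != "identity"))
      if (length(prev) >= 1 && is.finite(ms[prev[1]]) &&
          abs(ms[t] - ms[prev[1]]) < tol) break
    }
  }
  est_steps <- which(se$schedule[1:t_done] != "identity")
  final_t <- if (length(est_steps)) est_steps[length(est_steps)] else t_done
  structure(list(
    algorithm = algorithm, n = n, snr = dataset$snr, seed = seed,
    iterates_u = U[, 1:(t_done + 1), drop = FALSE],
    iterates_f = Fm[, 1:t_done, drop = FALSE],
    onsager = se$onsager[1:t_done, 1:t_done, drop = FALSE],
    empirical_overlap = ov[1:(t_done + 1)],
    empirical_mse = ms[1:t_done],
    iterations = t_done, final_t = final_t,
    final_mse = ms[final_t], final_overlap = ov[final_t + 1],
    converged = !diverged && is.finite(ms[final_t]) && ms[final_t] <= 0.45,
    diverged = diverged, se = se), class = "bamp_run")
}

#' @export
print.bamp_run <- function(x, ...) {
  cat(sprintf("<%s run> n=%d lambda=%.4g iters=%d final MSE=%.5f (SE: %.5f) converged=%s\n",
              x$algorithm, x$n, x$snr, x$iterations, x$final_mse,
              x$se$mse[x$final_t], x$converged))
  invisible(x)
}

#' Run the BAMP algorithm on a spiked dataset
#'
#' Executes the recursion \eqn{f^t = J(Y)u^t - \sum_{i\le t} c_{t,i} u^i},
#' \eqn{u^{t+1} = g_{t+1}(f^t)} with the single-iterate posterior-mean
#' denoiser, using Onsager coefficients and channel parameters from the
#' state evolution.  \eqn{J(Y)u} is evaluated with \eqn{K} matrix-vector
#' products per iteration; no matrix powers are formed.  The informative
#' initialization \eqn{u^1 = \epsilon X^* + \sqrt{1-\epsilon^2}\, g}
#' (independent Gaussian \eqn{g}) realizes the positive-correlation
#' starting condition the theory assumes.
#'
#' @param dataset A \code{"spiked_dataset"}.
#' @param poly Preprocessing polynomial; defaults to [j_coefficients()] for
#'   \code{spec} at the dataset's SNR.
#' @param prior Signal prior (must match the dataset generation).
#' @param spec The noise [ensemble_spec()].
#' @param T_max,eps_init,tol As in [bamp_state_evolution()].
#' @param seed Seed for the initialization draw.
#' @param se Optionally a precomputed \code{"se_state"} (reused across
#'   trials).
#' @return A \code{"bamp_run"} with per-iteration empirical overlap and
#'   matrix MSE, the trajectory, and a convergence flag (trials whose final
#'   MSE is not finite or exceeds 1 are flagged diverged; final MSE above
#'   0.45 is flagged non-converged, mirroring the discard rule used in the
#'   phase-diagram experiments).
#' @export
bamp_run <- function(dataset, poly = NULL, prior, spec, T_max = 30,
                     eps_init = 0.8, tol = 1e-7, seed = 1, se = NULL) {
  stopifnot(inherits(dataset, "spiked_dataset"))
  if (is.null(se)) {
    if (is.null(poly)) poly <- j_coefficients(spec, dataset$snr)
    se <- bamp_state_evolution(spec, poly, prior, dataset$snr,
                               T_max = T_max, eps_init = eps_init, tol = tol)
  }
  amp_run_engine(dataset, se, seed, algorithm = "bamp", tol = tol)
}

#' Run the auxiliary AMP and check the power-matching condition
#'
#' Executes the multistage auxiliary AMP on the noise matrix (Eq. of the
#' construction: \eqn{\tilde z^s = Z\tilde u^s - \sum_i \bar b_{s,i}\tilde
#' u^i}) using the coefficients produced by the state evolution, and
#' verifies that its iterates reconstruct the powers of the data matrix:
#' \eqn{\|\tilde u^{K(t-1)+\ell} - Y^{\ell-1} u^t\|^2/N} should vanish as
#' \eqn{N} grows.  This is the strongest internal consistency check of the
#' Onsager derivation; it requires access to the noise matrix and the
#' signal, so it is a simulation diagnostic, not an inference algorithm.
#'
#' @param dataset A \code{"spiked_dataset"} (must carry \code{noise}).
#' @param se An \code{"se_state"} from [bamp_state_evolution()].
#' @param seed Initialization seed.
#' @return List with the auxiliary iterates, the stage map, the per-step
#'   matching errors and their maximum.
#' @export
auxiliary_amp <- function(dataset, se, seed = 1) {
  Z <- dataset$noise
  Y <- dataset$data
  X <- dataset$signal
  n <- dataset$n
  K <- se$K; Td <- se$T; KT <- K * Td
  sl <- sqrt(dataset$snr)
  set.seed(derive_seed(seed, "init"))
  u1 <- se$eps * X + sqrt(1 - se$eps^2) * stats::rnorm(n)
  Ut <- matrix(0, n, KT + 1); Ut[, 1] <- u1
  Zt <- matrix(0, n, KT)
  Fm <- matrix(0, n, Td)
  matching <- numeric(KT)
  stage_map <- data.frame(s = seq_len(KT),
                          t = (seq_len(KT) - 1L) %/% K + 1L,
                          l = (seq_len(KT) - 1L) %% K + 1L)
  upow <- u1                       # Y^{l-1} u^t along the direct route
  for (s in seq_len(KT)) {
    t <- stage_map$t[s]; l <- stage_map$l[s]
    if (l == 1) upow <- Ut[, (t - 1L) * K + 1L]
    matching[s] <- mean((Ut[, s] - upow)^2)
    zt <- as.numeric(Z %*% Ut[, s]) -
      as.numeric(Ut[, 1:s, drop = FALSE] %*% se$bbar[s, 1:s])
    Zt[, s] <- zt
    ## empirical signal overlap of the current iterate: using it makes the
    ## splitting  Y v = sqrt(lambda)/N X <X, v> + Z v  exact, so the
    ## matching error isolates the Onsager reconstruction itself (the state
    ## evolution uses the deterministic limit gamma_tab of this quantity)
    gam_emp <- sum(X * Ut[, s]) / n
    if (l < K) {
      Ut[, s + 1] <- sl * gam_emp * X + zt +
        as.numeric(Ut[, 1:s, drop = FALSE] %*% se$bbar[s, 1:s])
    } else {
      f <- numeric(n)
      if (K >= 2) for (k in 1:(K - 1)) {
        f <- f + se$cvec[k] * Ut[, (t - 1L) * K + k + 1L]
      }
      f <- f + se$cvec[K] * (sl * gam_emp * X + zt +
        as.numeric(Ut[, 1:s, drop = FALSE] %*% se$bbar[s, 1:s]))
      for (i in 1:t) f <- f - se$onsager[t, i] * Ut[, (i - 1L) * K + 1L]
      Fm[, t] <- f
      varsig <- as.numeric(Fm[, 1:t, drop = FALSE] %*% se$alphas[[t]])
      if (s < KT) Ut[, s + 1] <- se$channels[[t]]$h(varsig)
    }
    if (l < K) upow <- as.numeric(Y %*% upow)  # Y^l u^t for the next step
  }
  list(iterates_u = Ut, iterates_z = Zt, stage_map = stage_map,
       onsager_aux = se$bbar, matching = matching,
       max_matching = max(matching))
}

#' Gaussianity diagnostic for the BAMP iterates
#'
#' Tests the state-evolution contract that, conditioned on the signal, the
#' iterate \eqn{f^t} is Gaussian: the residual
#' \eqn{r^t = f^t - \mu_t X^*} should have mean 0, variance
#' \eqn{\Sigma_{tt}}, vanishing third moment and fourth moment
#' \eqn{3\Sigma_{tt}^2}.  Discrepancies are reported in units of their
#' Monte-Carlo standard errors.
#'
#' @param run A \code{"bamp_run"}.
#' @param signal The true signal vector.
#' @param se The matching \code{"se_state"} (defaults to \code{run$se}).
#' @return Data frame with one row per iteration and columns
#'   \code{mean_z}, \code{var_z}, \code{skew_z}, \code{kurt_z}: each
#'   statistic's deviation from its Gaussian target in standard-error
#'   units.
#' @export
gaussianity_diagnostic <- function(run, signal, se = run$se) {
  Td <- ncol(run$iterates_f)
  n <- length(signal)
  out <- data.frame(t = seq_len(Td), mean_z = NA_real_, var_z = NA_real_,
                    skew_z = NA_real_, kurt_z = NA_real_)
  for (t in seq_len(Td)) {
    r <- run$iterates_f[, t] - se$mu[t] * signal
    s2 <- se$Sigma[t, t]
    out$mean_z[t] <- mean(r) / sqrt(s2 / n)
    out$var_z[t] <- (mean(r^2) - s2) / (sqrt(2) * s2 / sqrt(n))
    out$skew_z[t] <- mean(r^3) / sqrt(15 * s2^3 / n)
    out$kurt_z[t] <- (mean(r^4) - 3 * s2^2) / sqrt(96 * s2^4 / n)
  }
  out
}
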