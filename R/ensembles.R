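## Noise ensembles, signal priors and spiked dataset generation.
##
## The observation model is
##     Y = sqrt(lambda)/N * X* X*^T + Z,
## where Z is an N x N symmetric rotationally invariant random matrix drawn
## from a trace ensemble exp(-N/2 Tr V(Z)).  Three potential families are
## supported:
##   * quartic  V(x) = mu x^2/2 + gamma x^4/4 with gamma = gamma(mu) chosen
##     so the limiting spectrum has unit variance (the SNR calibration),
##   * sextic   V(x) = xi x^6/6 with xi = 27/80 (unit variance),
##   * goe      V(x) = x^2/2, the Gaussian orthogonal ensemble (the only
##     member with independent entries).

#' Calibrated quartic coupling \eqn{\gamma(\mu)}
#'
#' For the quartic potential \eqn{V(x) = \mu x^2/2 + \gamma x^4/4}, returns
#' the quartic coupling that makes the limiting eigenvalue density have unit
#' second moment, so that \eqn{\lambda} is a meaningful signal-to-noise
#' ratio across the whole family.  In closed form
#' \deqn{\gamma(\mu) = (8 - 9\mu + \sqrt{64 - 144\mu + 108\mu^2 - 27\mu^3})/27,}
#' which interpolates from \eqn{\gamma(0) = 16/27} (purely quartic, most
#' structured) down to \eqn{\gamma(1) = 0} (Wigner).
#'
#' @param mu Quadratic coefficient, in \eqn{[0, 1]}.
#' @return The calibrated quartic coefficient (a nonnegative scalar).
#' @seealso [a_squared()], [ensemble_spec()]
#' @examples
#' gamma_of_mu(0)    # 16/27
#' gamma_of_mu(1)    # 0
#' @export
gamma_of_mu <- function(mu) {
  if (!is.numeric(mu) || any(mu < 0 | mu > 1))
    stop("mu must lie in [0, 1]; the unit-variance calibration is only defined there")
  (8 - 9 * mu + sqrt(64 - 144 * mu + 108 * mu^2 - 27 * mu^3)) / 27
}

#' Support half-width squared of the quartic spectral density
#'
#' The limiting density of the quartic ensemble is supported on
#' \eqn{[-2a, 2a]} with \eqn{a^2 = (\sqrt{\mu^2 + 12\gamma} - \mu)/(6\gamma)};
#' for \eqn{\gamma = 0} the Wigner limit \eqn{a^2 = 1/\mu} is returned.
#'
#' @param mu Quadratic coefficient (nonnegative).
#' @param gamma Quartic coefficient (nonnegative).
#' @return \eqn{a^2 > 0}.
#' @examples
#' a_squared(0, 16/27)   # 3/4
#' a_squared(1, 0)       # 1 (semicircle support [-2, 2])
#' @export
a_squared <- function(mu, gamma) {
  stopifnot(gamma >= 0)
  if (gamma == 0) {
    if (mu <= 0) stop("degenerate ensemble: mu and gamma cannot both vanish")
    return(1 / mu)
  }
  (sqrt(mu^2 + 12 * gamma) - mu) / (6 * gamma)
}

#' Noise ensemble specification
#'
#' Builds the full description of a noise family: the potential, the derived
#' constants (\code{gamma}, \code{xi}, \code{a_sq}) and the polynomial
#' \eqn{Q} such that the limiting spectral density is
#' \eqn{\rho(x) = Q(x)\sqrt{4a^2 - x^2}/(2\pi)} on \eqn{[-2a, 2a]}.
#' All families are calibrated to unit spectral variance.
#'
#' @param family One of \code{"quartic"}, \code{"sextic"}, \code{"goe"}.
#' @param mu Quadratic coefficient of the quartic potential (ignored for the
#'   other families); \code{mu = 1} recovers the GOE.
#' @return An object of class \code{"ensemble_spec"} with fields
#'   \code{family}, \code{mu}, \code{gamma}, \code{xi}, \code{a_sq},
#'   \code{q} (density polynomial, even powers), \code{vp} (coefficients of
#'   \eqn{V'} on odd powers) and \code{degree} (degree of \eqn{V}).
#' @examples
#' sp <- ensemble_spec("quartic", mu = 0)
#' sp$gamma          # 16/27
#' sp$a_sq           # 3/4
#' @export
ensemble_spec <- function(family = c("quartic", "sextic", "goe"), mu = 1) {
  family <- match.arg(family)
  spec <- switch(family,
    goe = {
      list(family = family, mu = 1, gamma = 0, xi = 0, a_sq = 1,
           q = 1, vp = 1, degree = 2L)
    },
    quartic = {
      stopifnot(length(mu) == 1L)
      g <- gamma_of_mu(mu)
      a2 <- a_squared(mu, g)
      if (g == 0) {
        list(family = "goe", mu = 1, gamma = 0, xi = 0, a_sq = 1,
             q = 1, vp = 1, degree = 2L)
      } else {
        list(family = family, mu = mu, gamma = g, xi = 0, a_sq = a2,
             q = c(mu + 2 * a2 * g, g), vp = c(mu, g), degree = 4L)
      }
    },
    sextic = {
      xi <- sextic_xi()
      sol <- one_cut_solve(c(0, 0, xi))
      list(family = family, mu = 0, gamma = 0, xi = xi, a_sq = sol$a_sq,
           q = sol$q, vp = sol$vp, degree = 6L)
    })
  structure(spec, class = "ensemble_spec")
}

#' @export
print.ensemble_spec <- function(x, ...) {
  cat(sprintf("<ensemble_spec> family=%s  mu=%.4g  gamma=%.6g  xi=%.6g\n",
              x$family, x$mu, x$gamma, x$xi))
  cat(sprintf("  support [-2a, 2a], a^2 = %.6g; potential degree %d\n",
              x$a_sq, x$degree))
  invisible(x)
}

#' Limiting spectral density of a noise ensemble
#'
#' Evaluates \eqn{\rho(x) = Q(x)\sqrt{4a^2 - x^2}/(2\pi)} (for the quartic
#' family, \eqn{Q(x) = \mu + 2a^2\gamma + \gamma x^2}).  Returns 0 outside
#' the support.
#'
#' @param x Numeric vector of evaluation points.
#' @param spec An [ensemble_spec()].
#' @return Density values, same length as \code{x}.
#' @export
rho_density <- function(x, spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  s2 <- 4 * spec$a_sq - x^2
  out <- numeric(length(x))
  inside <- s2 > 0
  out[inside] <- eval_even_poly(spec$q, x[inside]) * sqrt(s2[inside]) / (2 * pi)
  pmax(out, 0)
}

#' Signal prior specification
#'
#' All priors are normalized to unit second moment, so that \eqn{\lambda}
#' measures the spike strength in units of the noise variance.  The sparse
#' Rademacher prior places mass \eqn{1 - p} at 0 and \eqn{p/2} at
#' \eqn{\pm 1/\sqrt{p}}.
#'
#' @param kind One of \code{"rademacher"}, \code{"sparse_rademacher"},
#'   \code{"gaussian"}, \code{"spherical"}.
#' @param sparsity Nonzero fraction \eqn{p \in (0, 1]} for
#'   \code{"sparse_rademacher"}.
#' @return An object of class \code{"prior_spec"}; discrete priors carry
#'   \code{atoms} (support points) and \code{probs}.
#' @export
prior_spec <- function(kind = c("rademacher", "sparse_rademacher",
                                "gaussian", "spherical"),
                       sparsity = NULL) {
  kind <- match.arg(kind)
  out <- list(kind = kind, sparsity = sparsity, atoms = NULL, probs = NULL)
  if (kind == "rademacher") {
    out$atoms <- c(-1, 1); out$probs <- c(0.5, 0.5)
  } else if (kind == "sparse_rademacher") {
    if (is.null(sparsity) || sparsity <= 0 || sparsity > 1)
      stop("sparse_rademacher needs sparsity in (0, 1]")
    v <- 1 / sqrt(sparsity)
    out$atoms <- c(-v, 0, v)
    out$probs <- c(sparsity / 2, 1 - sparsity, sparsity / 2)
  }
  structure(out, class = "prior_spec")
}

#' Draw a signal vector from a prior
#'
#' @param prior A [prior_spec()].
#' @param n Dimension.
#' @param seed Integer seed (deterministic draw).
#' @return Length-\code{n} numeric vector; for the spherical prior the
#'   squared norm is exactly \code{n}.
#' @export
sample_signal <- function(prior, n, seed) {
  stopifnot(inherits(prior, "prior_spec"), n >= 1)
  set.seed(derive_seed(seed, "signal"))
  switch(prior$kind,
    rademacher = sample(c(-1, 1), n, replace = TRUE),
    sparse_rademacher = sample(prior$atoms, n, replace = TRUE, prob = prior$probs),
    gaussian = stats::rnorm(n),
    spherical = {
      g <- stats::rnorm(n)
      g * sqrt(n) / sqrt(sum(g^2))
    })
}

## Inverse-CDF sampler for the limiting spectral density: density tabulated
## on a fine grid over [-2a, 2a], CDF by cumulative trapezoid, inversion by
## monotone interpolation.
sample_rho_eigenvalues <- function(n, spec, grid_points = 1e4) {
  a <- sqrt(spec$a_sq)
  xs <- seq(-2 * a, 2 * a, length.out = grid_points)
  dens <- rho_density(xs, spec)
  cdf <- cumsum((dens[-1] + dens[-length(dens)]) / 2 * diff(xs))
  cdf <- c(0, cdf)
  cdf <- cdf / cdf[length(cdf)]
  u <- stats::runif(n)
  stats::approx(cdf, xs, xout = u, ties = "ordered")$y
}

## Haar-distributed orthogonal matrix: QR of a Gaussian matrix with the sign
## convention that the R diagonal is positive (otherwise the law is not Haar).
haar_orthogonal <- function(n) {
  qrd <- qr(matrix(stats::rnorm(n * n), n, n))
  Q <- qr.Q(qrd)
  d <- sign(diag(qr.R(qrd)))
  d[d == 0] <- 1
  sweep(Q, 2, d, `*`)
}

#' Randomized Hadamard-Walsh eigenbasis
#'
#' Deterministic Hadamard-Walsh matrix times a diagonal of i.i.d. Rademacher
#' signs, scaled to be orthogonal.  Used for the universality experiment in
#' place of a Haar basis: the resulting noise is *not* rotationally
#' invariant, yet the algorithms are predicted to behave identically.
#'
#' @param n Dimension, must be a power of 2.
#' @param seed Integer seed for the sign draw.
#' @return An \code{n x n} orthogonal matrix with entries \eqn{\pm 1/\sqrt n}.
#' @export
hadamard_eigenbasis <- function(n, seed) {
  if (!is_power_of_two(n)) stop("hadamard_eigenbasis needs n to be a power of 2")
  H <- matrix(1, 1, 1)
  while (nrow(H) < n) H <- rbind(cbind(H, H), cbind(H, -H))
  set.seed(derive_seed(seed, "basis"))
  s <- sample(c(-1, 1), n, replace = TRUE)
  sweep(H, 2, s, `*`) / sqrt(n)
}

#' Sample a structured noise matrix
#'
#' Draws \eqn{Z = O D O^T} with eigenvalues i.i.d. from the limiting
#' spectral density of the ensemble and \eqn{O} Haar-distributed (or the
#' randomized Hadamard-Walsh basis for universality experiments).  This
#' matches the trace ensemble in the only ways the asymptotic theory uses:
#' weak convergence of the spectrum to \eqn{\rho} with no outliers, and a
#' basis independent of the eigenvalues.  For \code{family = "goe"} with the
#' Haar basis, a Gaussian Wigner matrix (entry variance \eqn{1/n}
#' off-diagonal) is drawn directly, which is the exact finite-\eqn{n} law.
#'
#' @param n Dimension (at least 2).
#' @param spec An [ensemble_spec()].
#' @param seed Integer seed.
#' @param basis \code{"haar"} (default) or \code{"hadamard"}.
#' @return Exactly symmetric \code{n x n} matrix.
#' @export
sample_noise <- function(n, spec, seed, basis = c("haar", "hadamard")) {
  stopifnot(inherits(spec, "ensemble_spec"), n >= 2)
  basis <- match.arg(basis)
  if (spec$family == "goe" && basis == "haar") {
    set.seed(derive_seed(seed, "eigenvalues"))
    A <- matrix(stats::rnorm(n * n), n, n)
    return((A + t(A)) / sqrt(2 * n))
  }
  set.seed(derive_seed(seed, "eigenvalues"))
  ev <- sample_rho_eigenvalues(n, spec)
  O <- if (basis == "haar") {
    set.seed(derive_seed(seed, "basis"))
    haar_orthogonal(n)
  } else {
    hadamard_eigenbasis(n, seed)
  }
  Z <- O %*% (ev * t(O))
  (Z + t(Z)) / 2
}

#' Assemble a spiked dataset from signal and noise
#'
#' Forms \eqn{Y = \sqrt\lambda/n \, x x^T + Z}.  The rank-one part has
#' leading eigenvalue \eqn{\sqrt\lambda \, \|x\|^2/n \approx \sqrt\lambda}.
#'
#' @param signal Length-\code{n} signal vector \eqn{X^*}.
#' @param noise Symmetric \code{n x n} noise matrix.
#' @param snr Signal-to-noise ratio \eqn{\lambda \ge 0}.
#' @param seed Optional seed recorded for provenance.
#' @return Object of class \code{"spiked_dataset"} with fields \code{n},
#'   \code{snr}, \code{signal}, \code{noise}, \code{data}.
#' @export
assemble_data <- function(signal, noise, snr, seed = NA_integer_) {
  n <- length(signal)
  if (!is.matrix(noise) || nrow(noise) != n || ncol(noise) != n)
    stop("signal/noise dimension mismatch")
  if (snr < 0) stop("snr must be nonnegative")
  Y <- sqrt(snr) / n * tcrossprod(signal) + noise
  structure(list(n = n, snr = snr, signal = signal, noise = noise,
                 data = Y, seed = seed),
            class = "spiked_dataset")
}

#' Generate one spiked dataset
#'
#' Convenience wrapper tying together [sample_signal()], [sample_noise()]
#' and [assemble_data()] under one root seed with derived streams, so each
#' component can be regenerated independently.
#'
#' @param n Dimension.
#' @param snr \eqn{\lambda \ge 0}.
#' @param spec An [ensemble_spec()].
#' @param prior A [prior_spec()].
#' @param seed Root seed.
#' @param basis Noise eigenbasis, \code{"haar"} or \code{"hadamard"}.
#' @return A \code{"spiked_dataset"}.
#' @examples
#' sp <- ensemble_spec("quartic", mu = 0)
#' ds <- spiked_dataset(200, snr = 5, spec = sp,
#'                      prior = prior_spec("rademacher"), seed = 1)
#' @export
spiked_dataset <- function(n, snr, spec, prior, seed, basis = "haar") {
  x <- sample_signal(prior, n, seed)
  Z <- sample_noise(n, spec, seed, basis = basis)
  assemble_data(x, Z, snr, seed = seed)
}

#' @export
print.spiked_dataset <- function(x, ...) {
  cat(sprintf("<spiked_dataset> n=%d  snr=%.4g  seed=%s\n",
              x$n, x$snr, format(x$seed)))
  invisible(x)
}
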