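## Numerics on limiting spectral measures: moments, free cumulants,
## Stieltjes transform, BBP outlier/overlap theory, the sextic calibration
## and the rescaled spectral (PCA) estimator.

#' Spectral moment of an ensemble by quadrature
#'
#' Computes \eqn{m_k = \int x^k \rho(x) dx} by Gauss-Legendre quadrature
#' after the substitution \eqn{x = 2a\sin\phi}, which absorbs the square
#' root edge factor and makes the integrand smooth.
#'
#' @param spec An [ensemble_spec()].
#' @param k Moment order (nonnegative integer).
#' @param nodes Number of quadrature nodes.
#' @return The moment (odd moments vanish by symmetry).
#' @examples
#' spectral_moment(ensemble_spec("goe"), 4)              # Catalan number 2
#' spectral_moment(ensemble_spec("quartic", 0), 4)       # 27/16
#' @export
spectral_moment <- function(spec, k, nodes = 200) {
  stopifnot(inherits(spec, "ensemble_spec"), k >= 0)
  if (k %% 2 == 1) return(0)
  a <- sqrt(spec$a_sq)
  gl <- gauss_legendre(nodes, -pi / 2, pi / 2)
  x <- 2 * a * sin(gl$x)
  ## rho(x) dx = Q(x) * (2a cos phi) / (2 pi) * (2a cos phi dphi)
  f <- x^k * eval_even_poly(spec$q, x) * (2 * a * cos(gl$x))^2 / (2 * pi)
  sum(gl$w * f)
}

## Closed-form even moments through the Catalan expansion (used as the
## internal oracle and for the deep moment sequences).
spectral_moments_closed <- function(spec, kmax) {
  m2k <- one_cut_moments(spec$q, spec$a_sq, kmax %/% 2)
  m <- numeric(kmax + 1)
  m[seq(1, kmax + 1, by = 2)] <- m2k
  m   # m[j] = m_{j-1}
}

#' Free cumulants from a moment sequence
#'
#' Inverts the free moment-cumulant relation.  The moment series
#' \eqn{M(z) = \sum_n m_n z^n} satisfies
#' \eqn{M = 1 + \sum_s \kappa_s z^s M^s} (a generating-function form of the
#' sum over non-crossing partitions), which is solved order by order for the
#' cumulants.  The forward map is applied to the result as a consistency
#' check.
#'
#' @param moments Numeric vector \eqn{(m_0, m_1, \dots, m_n)} with
#'   \eqn{m_0 = 1}.
#' @return Free cumulants \eqn{(\kappa_1, \dots, \kappa_n)}.
#' @examples
#' ## unit semicircle: all free cumulants vanish except kappa_2 = 1
#' free_cumulants_from_moments(c(1, 0, 1, 0, 2, 0, 5))
#' @export
free_cumulants_from_moments <- function(moments) {
  if (abs(moments[1] - 1) > 1e-12) stop("m_0 = 1 must be supplied")
  n <- length(moments) - 1L
  if (n < 1L) return(numeric(0))
  kap <- numeric(n)
  ## Mpow[[s]] = coefficients of M(z)^s up to z^n (index j -> z^(j-1))
  Mpow <- vector("list", n)
  Mpow[[1]] <- moments
  if (n >= 2) for (s in 2:n) {
    Mpow[[s]] <- poly_mult_trunc(Mpow[[s - 1]], moments, n + 1L)
  }
  for (ord in 1:n) {
    acc <- 0
    if (ord >= 2) for (s in 1:(ord - 1)) {
      acc <- acc + kap[s] * Mpow[[s]][ord - s + 1L]
    }
    ## kappa_ord * z^ord * M^ord contributes kappa_ord * 1 at order z^ord
    kap[ord] <- moments[ord + 1L] - acc
  }
  mm <- moments_from_cumulants(kap)
  if (max(abs(mm - moments)) > 1e-8 * max(1, max(abs(moments))))
    stop("moment sequence is not numerically consistent with a free cumulant expansion")
  kap
}

#' Moments from free cumulants (forward map)
#'
#' @param kappa Free cumulants \eqn{(\kappa_1, \dots, \kappa_n)}.
#' @return Moments \eqn{(m_0, \dots, m_n)}.
#' @export
moments_from_cumulants <- function(kappa) {
  n <- length(kappa)
  m <- c(1, numeric(n))
  if (n == 0) return(m)
  for (ord in 1:n) {
    Mcur <- m[1:ord]           # coefficients known up to z^(ord-1)
    acc <- 0
    pw <- c(1, numeric(ord - 1))  # M^0 truncated
    for (s in 1:ord) {
      pw <- poly_mult_trunc(pw, Mcur, ord)   # M^s up to z^(ord-1)
      acc <- acc + kappa[s] * pw[ord - s + 1L]
    }
    m[ord + 1L] <- acc
  }
  m
}

poly_mult_trunc <- function(a, b, len) {
  out <- numeric(len)
  for (i in seq_along(a)) {
    jmax <- len - i + 1L
    if (jmax < 1L) break
    jb <- seq_len(min(length(b), jmax))
    out[i + jb - 1L] <- out[i + jb - 1L] + a[i] * b[jb]
  }
  out
}

## ---- closed-form Stieltjes transform ------------------------------------

## G(z) = (V'(z) - Q(z) sqrt(z^2 - 4 a^2)) / 2, analytic off the cut.
## Works for real z outside the support and for complex z (principal branch
## product sqrt(z - 2a) sqrt(z + 2a), which is the branch with G ~ 1/z).
stieltjes_closed <- function(spec, z) {
  a <- sqrt(spec$a_sq)
  s <- sqrt(as.complex(z - 2 * a)) * sqrt(as.complex(z + 2 * a))
  vprime <- odd_poly_eval(spec$vp, z)
  g <- (vprime - eval_even_poly_c(spec$q, z) * s) / 2
  if (is.numeric(z) && all(Im(g) == 0)) Re(g) else g
}

stieltjes_closed_deriv <- function(spec, z) {
  a <- sqrt(spec$a_sq)
  s <- sqrt(as.complex(z - 2 * a)) * sqrt(as.complex(z + 2 * a))
  vpp <- odd_poly_deriv_eval(spec$vp, z)
  qd <- even_poly_deriv_eval(spec$q, z)
  g <- (vpp - qd * s - eval_even_poly_c(spec$q, z) * z / s) / 2
  if (is.numeric(z) && all(Im(g) == 0)) Re(g) else g
}

odd_poly_eval <- function(vp, z) {
  out <- 0; z2 <- z * z
  for (j in rev(seq_along(vp))) out <- out * z2 + vp[j]
  out * z
}
odd_poly_deriv_eval <- function(vp, z) {
  out <- 0; z2 <- z * z
  for (j in rev(seq_along(vp))) out <- out * z2 + (2 * j - 1) * vp[j]
  out
}
eval_even_poly_c <- function(q, z) {
  out <- 0; z2 <- z * z
  for (i in rev(seq_along(q))) out <- out * z2 + q[i]
  out
}
even_poly_deriv_eval <- function(q, z) {
  out <- 0; z2 <- z * z
  if (length(q) >= 2) for (i in rev(seq(2, length(q)))) out <- out * z2 + (2 * (i - 1)) * q[i]
  out * z
}

#' Stieltjes transform of the limiting spectral density
#'
#' \eqn{G(z) = \int \rho(x)/(z - x)\,dx} for real \eqn{z} outside the
#' support, computed by Gauss-Legendre quadrature with the
#' \eqn{x = 2a\sin\phi} substitution.  \eqn{G} is strictly decreasing on
#' \eqn{(2a, \infty)} with \eqn{G(z) \sim 1/z}; its value at the edge is
#' finite (soft edge).
#'
#' @param spec An [ensemble_spec()].
#' @param z Evaluation point(s), \eqn{|z| > 2a}.
#' @param nodes Quadrature nodes.
#' @return \eqn{G(z)}.
#' @export
stieltjes_transform <- function(spec, z, nodes = 400) {
  stopifnot(inherits(spec, "ensemble_spec"))
  a <- sqrt(spec$a_sq)
  if (any(abs(z) < 2 * a - 1e-12))
    stop("z inside the spectral support [-2a, 2a]")
  gl <- gauss_legendre(nodes, -pi / 2, pi / 2)
  x <- 2 * a * sin(gl$x)
  w <- gl$w * eval_even_poly(spec$q, x) * (2 * a * cos(gl$x))^2 / (2 * pi)
  vapply(z, function(zz) sum(w / (zz - x)), numeric(1))
}

## ---- free cumulants of an ensemble (deep, stable) -----------------------

## kappa_n are the Taylor coefficients of the R-transform
## R(w) = G^{-1}(w) - 1/w = sum_{n>=1} kappa_n w^{n-1}.  G maps the slit
## plane bijectively onto the region bounded by the curve
## G(x + i0) = V'(x)/2 - i pi rho(x), x in the cut, so R is analytic on the
## disk |w| < r_c = min_x |V'(x)/2 - i pi rho(x)| (the cumulants grow like
## r_c^{-n}; a plain moment->cumulant recursion in doubles loses them to
## cancellation beyond order ~50).  They are extracted by a Cauchy integral
## over the circle |w| = r < r_c: the FFT of R on the circle gives every
## order at once with absolute error ~ eps * max|R| * r^{-(n-1)}, which
## stays far below |kappa_n| ~ r_c^{-(n-1)}.  G^{-1} is evaluated by Newton
## continuation around the circle starting from the real solution, using
## the closed-form G and G'.
.kappa_cache <- new.env(parent = emptyenv())

#' Free cumulants of a noise ensemble
#'
#' Returns \eqn{(\kappa_1, \dots, \kappa_{order})} of the limiting spectral
#' measure.  These parametrize the Onsager corrections of all AMP variants.
#' Computed from the R-transform via a Cauchy integral on a circle inside
#' its disk of analyticity, which stays accurate at the large orders the
#' multistage state evolution consumes (the moment-recursion route loses
#' those orders to cancellation).
#'
#' @param spec An [ensemble_spec()].
#' @param order Highest cumulant order wanted.
#' @return Numeric vector of length \code{order}; entries beyond machine
#'   resolution are exactly the tail of the analytic decay, odd entries are
#'   zero by symmetry.
#' @examples
#' kap <- free_cumulants(ensemble_spec("quartic", 0), 6)
#' kap[4]   # -5/16
#' kap[6]   # 1/4
#' @export
free_cumulants <- function(spec, order) {
  stopifnot(inherits(spec, "ensemble_spec"), order >= 1)
  if (spec$family == "goe") {
    out <- numeric(order); if (order >= 2) out[2] <- 1
    return(out)
  }
  key <- paste(spec$family, spec$mu, order, sep = "_")
  if (!is.null(.kappa_cache[[key]])) return(.kappa_cache[[key]])
  a <- sqrt(spec$a_sq)
  ## radius of analyticity of R: distance from 0 to the image of the cut
  xs <- seq(0, 2 * a, length.out = 2048)
  bdry <- sqrt((odd_poly_eval(spec$vp, xs) / 2)^2 + (pi * rho_density(xs, spec))^2)
  r <- 0.8 * min(bdry)
  M <- 8192L
  th <- 2 * pi * (0:(M - 1)) / M
  w <- r * exp(1i * th)
  ## real starting point: solve G(z) = r on (2a, inf)
  f <- function(z) Re(stieltjes_closed(spec, z)) - r
  hi <- 2 * a + 1
  while (f(hi) > 0) hi <- hi * 2
  z0 <- stats::uniroot(f, c(2 * a + 1e-12, hi), tol = 1e-15)$root
  zs <- complex(M)
  z <- z0
  for (j in seq_len(M)) {
    ## Newton refinement of G(z) = w[j], warm-started along the circle
    for (it in 1:60) {
      gz <- stieltjes_closed(spec, z)
      dz <- (gz - w[j]) / stieltjes_closed_deriv(spec, z)
      z <- z - dz
      if (abs(dz) < 1e-14 * max(1, abs(z))) break
    }
    if (abs(stieltjes_closed(spec, z) - w[j]) > 1e-9)
      stop("R-transform continuation failed at angle ", th[j])
    zs[j] <- z
  }
  Rvals <- zs - 1 / w
  cf <- stats::fft(Rvals) / M
  ns <- seq_len(order)
  kap <- Re(cf[ns]) / r^(ns - 1)
  kap[abs(kap) < 1e-13] <- 0
  ## symmetric measures have no odd cumulants
  kap[seq(1, order, by = 2)] <- 0
  .kappa_cache[[key]] <- kap
  kap
}

## ---- sextic calibration --------------------------------------------------

#' Sextic potential coefficient with unit spectral variance
#'
#' Solves the one-cut equilibrium problem for the pure sextic potential
#' \eqn{V(x) = \xi x^6/6} (density
#' \eqn{(c_0 + c_2 x^2 + c_4 x^4)\sqrt{4a^2 - x^2}/(2\pi)}, coefficients
#' fixed by the potential-to-density relations and normalization) and
#' returns the \eqn{\xi} for which the measure has unit second moment.
#'
#' @return \eqn{\xi = 27/80} to numerical tolerance.
#' @examples
#' sextic_xi()           # 0.3375
#' @export
sextic_xi <- function() {
  calibrate_unit_variance(function(xi) c(0, 0, xi))
}

## same machinery, exposed for cross-validation: the unit-variance quartic
## coupling at fixed mu, and the quadratic coefficient (which must be 1).
calibrate_quartic_gamma <- function(mu) {
  if (mu >= 1) {
    ## at mu = 1 the solution is gamma = 0 (pure semicircle); detect by limit
    f <- function(g) one_cut_solve(c(mu, g), kmax = 1)$moments[2] - 1
    ## m2 at gamma -> 0+ equals 1/mu^2; root is 0 when mu = 1
    if (abs(f(1e-12)) < 1e-6) return(0)
  }
  calibrate_unit_variance(function(g) c(mu, g))
}
calibrate_quadratic <- function() {
  calibrate_unit_variance(function(cc) cc)
}

## ---- BBP outlier / overlap theory ---------------------------------------

#' BBP outlier location and eigenvector overlap
#'
#' For the spiked model \eqn{Y = \sqrt\lambda/N X^* X^{*T} + Z} the top
#' eigenvalue detaches from the bulk when
#' \eqn{\sqrt\lambda > 1/G_\rho(2a)}.  Above the threshold the outlier
#' solves \eqn{G_\rho(z^*) = 1/\sqrt\lambda} and the squared overlap of the
#' top eigenvector with \eqn{X^*/\sqrt N} is
#' \eqn{\varepsilon^2 = -1/(\lambda\, G_\rho'(z^*))} (standard additive
#' finite-rank deformation theory).
#'
#' @param spec An [ensemble_spec()].
#' @param snr \eqn{\lambda \ge 0}.
#' @return List with \code{snr}, \code{outlier} (\eqn{z^*}; the edge
#'   \eqn{2a} below threshold), \code{overlap_sq} (\eqn{\varepsilon^2}, 0
#'   below threshold), \code{above_threshold}, and \code{snr_threshold}
#'   (\eqn{\lambda_c = 1/G_\rho(2a)^2}).
#' @examples
#' bbp_theory(ensemble_spec("goe"), 4)   # z* = 2.5, overlap 0.75
#' @export
bbp_theory <- function(spec, snr) {
  stopifnot(inherits(spec, "ensemble_spec"), snr >= 0)
  a <- sqrt(spec$a_sq)
  gedge <- stieltjes_closed(spec, 2 * a)
  lc <- 1 / gedge^2
  if (snr <= lc) {
    return(list(snr = snr, outlier = 2 * a, overlap_sq = 0,
                above_threshold = FALSE, snr_threshold = lc))
  }
  target <- 1 / sqrt(snr)
  f <- function(z) stieltjes_closed(spec, z) - target
  hi <- max(2 * sqrt(snr), 2 * a + 1)
  while (f(hi) > 0) hi <- hi * 2
  zstar <- stats::uniroot(f, c(2 * a + 1e-13, hi), tol = 1e-14)$root
  eps2 <- -1 / (snr * stieltjes_closed_deriv(spec, zstar))
  list(snr = snr, outlier = zstar, overlap_sq = min(max(eps2, 0), 1),
       above_threshold = TRUE, snr_threshold = lc)
}

## ---- rescaled spectral (PCA) estimator ----------------------------------

## Top (largest) eigenvalue/eigenvector by two-phase power iteration:
## first find the dominant eigenvalue in absolute value; if it is negative,
## rerun on Y + |lambda_min| I, whose spectrum is nonnegative with the same
## eigenvectors.  The shift stays O(spectral radius), so convergence is
## geometric with an O(1) rate (a Gershgorin-type shift would be O(sqrt n)
## here and make the iteration crawl).  O(n^2) per matvec.
top_eigenvector <- function(Y, tol = 1e-10, max_iter = 3000) {
  n <- nrow(Y)
  power_phase <- function(shift) {
    v <- stats::rnorm(n)
    v <- v / sqrt(sum(v^2))
    lam_old <- Inf
    for (i in seq_len(max_iter)) {
      w <- as.numeric(Y %*% v) + shift * v
      v <- w / sqrt(sum(w^2))
      if (i %% 5 == 0) {
        lam <- sum(v * (as.numeric(Y %*% v)))
        if (abs(lam - lam_old) < tol * max(1, abs(lam))) break
        lam_old <- lam
      }
    }
    list(vector = v, value = sum(v * (as.numeric(Y %*% v))))
  }
  p1 <- power_phase(0)
  if (p1$value >= 0) return(p1)
  power_phase(abs(p1$value) + 0.1)
}

#' Rescaled spectral (PCA) estimator of the spike
#'
#' The naive PCA estimator of \eqn{P^* = X^* X^{*T}} rescaled by
#' \eqn{C = N\varepsilon^2(\lambda)}: returns \eqn{C\,\nu\nu^T} with
#' \eqn{\nu} the unit top eigenvector.  Its asymptotic matrix mean-square
#' error \eqn{\|P^* - C\nu\nu^T\|_F^2/(2N^2)} is \eqn{(1-\varepsilon^4)/2}.
#' Below the BBP threshold the estimator is the zero matrix.
#'
#' @param dataset A \code{"spiked_dataset"}.
#' @param spec The [ensemble_spec()] the noise was drawn from.
#' @return List with \code{C} (scalar rescaling), \code{nu} (unit top
#'   eigenvector), \code{top_eigenvalue}, \code{below_threshold} flag, and
#'   \code{mse} (matrix MSE against the dataset's true spike).
#' @export
spectral_pca_estimate <- function(dataset, spec) {
  stopifnot(inherits(dataset, "spiked_dataset"))
  n <- dataset$n
  th <- bbp_theory(spec, dataset$snr)
  if (!th$above_threshold) {
    mse <- 0.5 * (sum(dataset$signal^2) / n)^2
    warning("SNR below the BBP threshold: returning the zero estimator")
    return(list(C = 0, nu = rep(0, n), top_eigenvalue = NA_real_,
                below_threshold = TRUE, mse = mse))
  }
  set.seed(derive_seed(if (is.na(dataset$seed)) 0L else dataset$seed, "extra"))
  pe <- top_eigenvector(dataset$data)
  C <- n * th$overlap_sq
  ## ||P* - C nu nu^T||_F^2 / (2 n^2) via inner products only
  s2 <- sum(dataset$signal^2)
  sv <- sum(dataset$signal * pe$vector)
  mse <- (s2^2 - 2 * C * sv^2 + C^2) / (2 * n^2)
  list(C = C, nu = pe$vector, top_eigenvalue = pe$value,
       below_threshold = FALSE, mse = mse)
}
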