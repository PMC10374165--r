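## One-cut equilibrium measures of even polynomial matrix potentials.
##
## For a trace ensemble with potential V whose derivative is the odd
## polynomial V'(z) = sum_j vp[j] z^(2j-1), the limiting eigenvalue density
## on a single symmetric cut [-2a, 2a] has the form
##
##   rho(x) = Q(x) * sqrt(4 a^2 - x^2) / (2 pi),   Q even, deg Q = deg V' - 1,
##
## and the Stieltjes transform is G(z) = (V'(z) - Q(z) sqrt(z^2 - 4a^2)) / 2.
## Matching the positive powers of z fixes Q given a^2 (triangular system),
## and G(z) ~ 1/z fixes a^2 (normalization).  Spectral moments then come out
## in closed form through Catalan numbers:
##   m_{2k} = sum_i q_{2i} Cat(k+i) a^{2(k+i+1)}.

## Solve for the density polynomial Q given the half-width squared a2.
## vp: coefficients of V' on odd powers z^1, z^3, ..., z^(2p-1) (length p).
## Returns q: coefficients of Q on even powers x^0, x^2, ..., x^(2p-2).
one_cut_qpoly <- function(vp, a2) {
  p <- length(vp)
  ## sigma_k: series z*sqrt(1-4a2/z^2) = sum_k sigma_k a2^k z^(1-2k)
  sig <- c(1, -2 * catalan(0:(2 * p)))          # sigma_0 .. sigma_{2p+1}
  q <- numeric(p)
  ## match coefficient of z^(2j-1): sum_{i >= j-1} q_i sigma_{i-j+1} a2^(i-j+1) = vp_j
  for (j in p:1) {
    acc <- 0
    if (j <= p - 1) {
      for (i in j:(p - 1)) {                     # q index i -> power x^(2i)
        acc <- acc + q[i + 1] * sig[i - j + 2] * a2^(i - j + 1)
      }
    }
    q[j] <- (vp[j] - acc) / sig[1]               # sigma_0 = 1, q index j-1
  }
  q
}

## Closed-form even spectral moments m_0, m_2, ..., m_{2kmax}
one_cut_moments <- function(q, a2, kmax) {
  p <- length(q)
  m <- numeric(kmax + 1)
  for (k in 0:kmax) {
    i <- 0:(p - 1)
    m[k + 1] <- sum(q * catalan(k + i) * a2^(k + i + 1))
  }
  m
}

## Normalization m_0(a2) = 1 determines a2; m_0 is increasing in a2 for
## admissible potentials, so a bisection bracket is easy to grow.
one_cut_a2 <- function(vp) {
  f <- function(a2) one_cut_moments(one_cut_qpoly(vp, a2), a2, 0)[1] - 1
  lo <- 1e-8
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  while (f(lo) > 0) lo <- lo / 2
  stats::uniroot(f, c(lo, hi), tol = 1e-14)$root
}

## Full solve: density polynomial, support, moments; checks one-cut validity
## (Q must be nonnegative on the support, otherwise the ansatz is wrong).
one_cut_solve <- function(vp, kmax = 8) {
  a2 <- one_cut_a2(vp)
  q <- one_cut_qpoly(vp, a2)
  xs <- seq(0, 2 * sqrt(a2), length.out = 512)
  if (min(eval_even_poly(q, xs)) < -1e-10)
    stop("one-cut ansatz invalid: density polynomial negative on support")
  list(a_sq = a2, q = q, vp = vp,
       moments = one_cut_moments(q, a2, kmax))
}

## Calibrate a single-parameter potential family so that the equilibrium
## measure has unit second moment (the SNR convention).  `vp_of` maps the
## free parameter to the V' coefficient vector.
calibrate_unit_variance <- function(vp_of, lower = 1e-8, upper = 64) {
  m2 <- function(theta) {
    sol <- one_cut_solve(vp_of(theta), kmax = 1)
    sol$moments[2] - 1
  }
  ## m2 is decreasing in the potential strength for the families used here
  stats::uniroot(m2, c(lower, upper), tol = 1e-13)$root
}
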