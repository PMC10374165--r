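## Internal helpers: seeding, quadrature, small numerics.

## Deterministic 32-bit sub-seed derivation so that the eigenvalue draw, the
## eigenbasis draw and the signal draw of one dataset come from independent,
## individually reproducible streams.
derive_seed <- function(root, stream) {
  stopifnot(is.numeric(root), length(root) == 1L, is.finite(root))
  streams <- c(eigenvalues = 101L, basis = 211L, signal = 307L, init = 401L,
               trial = 503L, extra = 601L)
  off <- if (is.character(stream)) {
    if (!stream %in% names(streams)) stop("unknown stream: ", stream)
    streams[[stream]]
  } else as.integer(stream)
  ## multiplicative hash mod a prime below 2^31
  p <- 2147483587
  s <- (abs(root) %% p)
  s <- (s * 48271 + off * 16807 + 12345) %% p
  as.integer(s) + 1L
}

catalan <- function(k) choose(2 * k, k) / (k + 1)

## Gauss-Legendre nodes/weights cache
.quad_cache <- new.env(parent = emptyenv())
gauss_legendre <- function(n, a = -1, b = 1) {
  key <- paste0("gl", n)
  gl <- .quad_cache[[key]]
  if (is.null(gl)) {
    gl <- pracma::gaussLegendre(n, -1, 1)
    .quad_cache[[key]] <- gl
  }
  list(x = (a + b) / 2 + (b - a) / 2 * gl$x, w = (b - a) / 2 * gl$w)
}

## Gauss-Hermite in probabilists' convention: E[f(G)] with G ~ N(0,1)
gauss_hermite_prob <- function(n = 61) {
  key <- paste0("gh", n)
  gh <- .quad_cache[[key]]
  if (is.null(gh)) {
    g <- pracma::gaussHermite(n)
    gh <- list(x = g$x * sqrt(2), w = g$w / sqrt(pi))
    .quad_cache[[key]] <- gh
  }
  gh
}

## Evaluate an even polynomial sum_i q[i+1] * x^(2i)
eval_even_poly <- function(q, x) {
  out <- 0
  x2 <- x * x
  for (i in rev(seq_along(q))) out <- out * x2 + q[i]
  out
}

is_power_of_two <- function(n) n >= 1 && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L
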