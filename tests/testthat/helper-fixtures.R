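## Shared fixtures, built lazily and cached so the expensive objects
## (n = 2000 datasets, state evolutions) are constructed once per test run.

.fx <- new.env(parent = emptyenv())

fx_quartic0 <- function() ensemble_spec("quartic", mu = 0)
fx_rademacher <- function() prior_spec("rademacher")

## one moderate quartic dataset reused by several structural tests
fx_dataset_small <- function() {
  if (is.null(.fx$ds_small))
    .fx$ds_small <- spiked_dataset(600, snr = 5, fx_quartic0(),
                                   fx_rademacher(), seed = 42)
  .fx$ds_small
}

## the criterion-scale fixture: quartic mu=0, lambda=5, n=2000, 10 seeds
fx_phase_datasets <- function(nseeds = 10, n = 2000) {
  key <- paste0("phase_", n, "_", nseeds)
  if (is.null(.fx[[key]])) {
    .fx[[key]] <- lapply(seq_len(nseeds), function(i)
      spiked_dataset(n, snr = 5, fx_quartic0(), fx_rademacher(),
                     seed = 1000 + i))
  }
  .fx[[key]]
}

fx_bamp_se5 <- function() {
  if (is.null(.fx$bamp_se5))
    .fx$bamp_se5 <- bamp_state_evolution(fx_quartic0(),
                                         j_coefficients(fx_quartic0(), 5),
                                         fx_rademacher(), snr = 5,
                                         T_max = 20)
  .fx$bamp_se5
}

fx_ap_se5 <- function() {
  if (is.null(.fx$ap_se5))
    .fx$ap_se5 <- amp_state_evolution(fx_quartic0(), fx_rademacher(), 5,
                                      "amp_ap", T_max = 12)
  .fx$ap_se5
}

## scalar spiked-Wigner state evolution, the independent oracle for the
## GOE reduction: m_{t+1} = E[X tanh(lambda m + sqrt(lambda m) G)]
wigner_se_oracle <- function(lambda, eps = 0.8, iters = 400, tol = 1e-13) {
  m <- eps^2
  for (t in seq_len(iters)) {
    mn <- stats::integrate(function(g) stats::dnorm(g) *
                             tanh(lambda * m + sqrt(lambda * m) * g),
                           -12, 12, rel.tol = 1e-13)$value
    if (abs(mn - m) < tol) break
    m <- mn
  }
  m
}

## brute-force free moments from cumulants: sum over all non-crossing set
## partitions, enumerated explicitly.  A partition given as a label vector
## p crosses iff some a < b < c < d has p[a] = p[c] != p[b] = p[d].
nc_partitions <- function(n) {
  parts <- list()
  rgs <- function(prefix, mx) {
    if (length(prefix) == n) {
      parts[[length(parts) + 1]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(mx + 1)) rgs(c(prefix, v), max(mx, v))
  }
  rgs(1L, 1L)
  if (n < 4) return(parts)
  quads <- utils::combn(n, 4)
  Filter(function(p) {
    !any(p[quads[1, ]] == p[quads[3, ]] &
         p[quads[2, ]] == p[quads[4, ]] &
         p[quads[1, ]] != p[quads[2, ]])
  }, parts)
}

moments_by_enumeration <- function(kappa, nmax) {
  vapply(seq_len(nmax), function(n) {
    ps <- nc_partitions(n)
    sum(vapply(ps, function(p) {
      sizes <- tabulate(p)
      prod(kappa[sizes[sizes > 0]])
    }, numeric(1)))
  }, numeric(1))
}
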