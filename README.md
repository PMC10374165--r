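# structpca

Estimating a rank-one "spike" buried in a large symmetric noise matrix is
the canonical high-dimensional inference problem behind probabilistic PCA,
community detection and group synchronization.  Theory almost always
assumes the noise is a Wigner matrix — independent Gaussian entries.
`structpca` is a toolkit for the *structured* case: the noise is drawn from
a rotationally invariant trace ensemble
`P(Z) ∝ exp(−(N/2) Tr V(Z))` with a non-quadratic polynomial potential
`V`, whose entries are dependent.  The observation model is

    Y = sqrt(λ)/N · X* X*ᵀ + Z,     E[X*_i²] = 1,

with the spectrum of `Z` calibrated to unit variance so that `λ` is a
genuine signal-to-noise ratio.  The package is aimed at researchers in
high-dimensional statistics and random matrix theory who want to
generate these models, compute their spectral theory, and compare
estimators against the information-theoretic benchmark.

What it provides:

* **Ensembles and data** — calibrated quartic (`V = μx²/2 + γ(μ)x⁴/4`,
  `γ(0) = 16/27` down to the GOE at `μ = 1`), pure sextic
  (`V = ξx⁶/6`, `ξ = 27/80`) and GOE families; signal priors
  (Rademacher, sparse Rademacher, Gaussian, spherical); reproducible
  spiked datasets, including a Hadamard–Walsh eigenbasis swap for
  universality experiments.
* **Spectral theory** — one-cut equilibrium measures, moments, free
  cumulants (stable to order 100+ via a Cauchy integral of the
  R-transform), Stieltjes transforms, and the BBP outlier/overlap theory
  with the rescaled PCA estimator `C·ννᵀ`, `C = N·ε²(λ)`.
* **Optimal preprocessing** — the polynomial
  `J(Y) = μ√λ·Y − γλ·Y² + γ√λ·Y³` (and its sextic analogue) that maps the
  noise bulk to the negative axis while amplifying the signal outlier.
* **Algorithms** — BAMP, the Bayes-optimal approximate message passing
  recursion `fᵗ = J(Y)uᵗ − Σᵢ c_{t,i} uⁱ`, `uᵗ⁺¹ = g_{t+1}(fᵗ)`, with
  Onsager coefficients and per-iteration error predictions from a
  multistage state evolution (an auxiliary AMP that tracks every power
  `Yᵏuᵗ` through free-cumulant Onsager corrections); plus the baselines:
  rotationally-invariant AMP with single-iterate posterior mean,
  full-memory posterior-mean AMP, and AMP with alternating posteriors
  (AMP-AP), which matches BAMP without ever being told `J`.
* **Experiments** — MSE-versus-SNR phase diagrams with state-evolution
  theory curves, the spectral-cleaning demo, and Haar-vs-Hadamard
  universality comparisons, with per-trial seeds and explicit
  non-convergence accounting.

## Worked example

Most structured quartic noise (`μ = 0`), Rademacher signal, `λ = 5`:

```r
library(structpca)

spec  <- ensemble_spec("quartic", mu = 0)
prior <- prior_spec("rademacher")
spec
#> <ensemble_spec> family=quartic  mu=0  gamma=0.592593  xi=0
#>   support [-2a, 2a], a^2 = 0.75; potential degree 4

theory <- bbp_theory(spec, snr = 5)
#> BBP threshold 0.4219; outlier z* = 2.6591; overlap^2 = 0.8297

ds <- spiked_dataset(n = 2000, snr = 5, spec = spec, prior = prior, seed = 1)
se <- bamp_state_evolution(spec, j_coefficients(spec, 5), prior, snr = 5)
se
#> <se_state> bamp  K=3  lambda=5  T=14  converged=TRUE
#>   final overlap m=0.973443  MSE=0.026204

run <- bamp_run(ds, prior = prior, spec = spec, seed = 1, se = se)
run
#> <bamp run> n=2000 lambda=5 iters=14 final MSE=0.01965 (SE: 0.02620) converged=TRUE
```

The state evolution predicts the asymptotic matrix mean-square error
`‖X*X*ᵀ − ûûᵀ‖²_F/(2N²)` of the BAMP estimate: here `0.0262`, reached in
about ten iterations; the empirical run at `n = 2000` lands within
finite-size fluctuation of it.  The baselines on the same dataset show
what the noise structure is worth:

```r
base <- riamp_run(ds, prior, spec, seed = 1)
#> single-iterate AMP on raw Y: final MSE 0.0413 (SE 0.0415)
pca <- spectral_pca_estimate(ds, spec)
#> rescaled PCA: MSE 0.1556 (theory 0.1558)
```

So at `λ = 5` the spectral estimator pays `0.156`, the standard
rotationally-invariant AMP `0.042`, and BAMP — by actually *using* the
noise dependencies through `J(Y)` — `0.026`.  A full phase diagram over an
SNR grid, with per-`λ` state-evolution curves and non-convergence counts:

```r
cfg <- experiment_config(family = "quartic", mu = 0, snr_grid = c(4, 5, 6),
                         n = 2000, trials = 10,
                         algorithms = c("bamp", "riamp_single", "pca"))
rt <- run_phase_diagram(cfg)
write_result_table(rt, "phase_diagram")
```

A thin command-line wrapper over the same functions is included at
`inst/scripts/spca.R` (`simulate`, `theory`, `specdemo`, `phase` subcommands).

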