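---
title: "Methods: spiked matrix estimation under structured noise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spiked matrix estimation under structured noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structpca)
```

## The model

The package studies rank-one estimation from a symmetric data matrix

$$Y \;=\; \frac{\sqrt{\lambda}}{N}\,X^{*}X^{*\mathsf T} \;+\; Z,
\qquad X^{*}\in\mathbb R^{N},$$

where the signal prior has unit second moment (so $\lambda$ is a
signal-to-noise ratio) and the noise $Z$ is drawn from a *trace ensemble*
$\propto \exp(-\tfrac N2\,\mathrm{Tr}\,V(Z))$.  Such noise is rotationally
invariant but, for any non-quadratic potential $V$, its entries are
*dependent*: the noise has structure.  The package asks, and answers
operationally, how much of that structure an estimation algorithm can
exploit.

Three potentials are built in:

* **quartic** $V(x) = \mu x^2/2 + \gamma x^4/4$, where $\mu \in [0,1]$
  interpolates from the most structured member ($\mu=0$) to the Gaussian
  orthogonal ensemble ($\mu = 1$);
* **sextic** $V(x) = \xi x^6/6$;
* **goe** $V(x) = x^2/2$, the only member with independent entries.

Each family is *calibrated*: the free coefficient ($\gamma(\mu)$, $\xi$) is
fixed so that the limiting spectral density has unit second moment,
otherwise $\lambda$ would not be comparable across families.  For the
quartic family
$\gamma(\mu) = (8-9\mu+\sqrt{64-144\mu+108\mu^2-27\mu^3})/27$, so
$\gamma(0)=16/27$ and $\gamma(1)=0$; for the sextic family $\xi = 27/80$.
The package recomputes both from the generic one-cut equilibrium-measure
solver rather than trusting the closed forms (they agree to $10^{-8}$;
`sextic_xi()`, `spectral_moment()`).

### One-cut equilibrium measures

For an even polynomial potential with derivative $V'$, the limiting
eigenvalue density on a single cut $[-2a, 2a]$ is
$\rho(x) = Q(x)\sqrt{4a^2-x^2}/(2\pi)$ with $Q$ a polynomial determined by
matching $G(z) = (V'(z) - Q(z)\sqrt{z^2-4a^2})/2$ to the $1/z$ tail of a
Stieltjes transform.  This yields, in closed form, the density polynomial,
the support, all spectral moments (through Catalan numbers), and $G$
itself.  The implementation checks one-cut validity by verifying $Q \ge 0$
on the support.  For the quartic family this machinery reproduces the
printed constants $a^2 = (\sqrt{\mu^2+12\gamma}-\mu)/(6\gamma)$ and
$\rho(x)=(\mu + 2a^2\gamma + \gamma x^2)\sqrt{4a^2-x^2}/(2\pi)$.

## Synthetic data

`spiked_dataset()` draws $Z = ODO^{\mathsf T}$ with eigenvalues i.i.d.
from $\rho$ (inverse-CDF on a $10^4$-point tabulation) and $O$ Haar
(QR of a Gaussian matrix with the positive-diagonal sign fix).  The
asymptotic theory uses only weak convergence of the spectrum with no
outliers and independence of basis and eigenvalues, both of which this
sampler delivers; exact finite-$N$ sampling of the trace ensemble (a
log-gas) is deliberately out of scope.  For GOE noise a dense Gaussian
Wigner matrix is drawn directly, which *is* the exact finite-$N$ law.  For
universality experiments the Haar basis can be swapped for the
Hadamard–Walsh matrix times random signs (`basis = "hadamard"`), which is
far from rotationally invariant.

What the generator does **not** emulate: eigenvalue repulsion and edge
fluctuations of the true trace ensemble (i.i.d. draws have
$O(N^{-1/2})$ spectral fluctuations instead of $O(N^{-1})$), heavy-tailed
or banded noise, rank $>1$ spikes, and real-data eigenbases.  Tests
passing on this generator therefore support the rotational-invariance
theory and its Hadamard universality, not robustness beyond it.

Priors (`prior_spec()`): Rademacher, sparse Rademacher (values
$\pm 1/\sqrt p$, forced by the unit-second-moment convention), standard
Gaussian, and the uniform sphere of squared radius $N$.  Seeding derives
separate substreams for eigenvalues, basis and signal from one root seed,
so each component can be regenerated independently.

## Spectral theory

`bbp_theory()` implements the additive finite-rank deformation results:
with $\theta = \sqrt\lambda$, the top eigenvalue detaches iff
$\theta > 1/G(2a)$, the outlier solves $G(z^{*}) = 1/\theta$, and the
squared eigenvector overlap is $\varepsilon^2 = -1/(\lambda G'(z^{*}))$.
The generic path was verified against the spiked-Wigner closed forms
($z^{*} = \sqrt\lambda + 1/\sqrt\lambda$, $\varepsilon^2 = 1-1/\lambda$)
before use.  `spectral_pca_estimate()` returns the rescaled PCA estimator
$C\nu\nu^{\mathsf T}$ with $C = N\varepsilon^2$, whose matrix MSE tends to
$(1-\varepsilon^4)/2$; for rotationally invariant (spherical) priors this
is the natural benchmark, and the zero matrix is returned below threshold.

### Free cumulants

Free cumulants of $\rho$ parametrize every Onsager correction in the
package.  Two routes are provided.
`free_cumulants_from_moments()` inverts the non-crossing-partition
moment–cumulant relation order by order; it is exact at low order and is
tested against a brute-force enumeration of non-crossing partitions up to
order 8.  But the state evolution needs cumulants to order
$2KT + 2 \approx 60$–$200$, and the recursion in double precision loses
them: the moments grow like $(2a)^n$ while the recursion's answer is the
small difference of large terms.  The cumulants themselves grow only like
$r_c^{-n}$, where $r_c = \min_x |V'(x)/2 - i\pi\rho(x)|$ is the radius of
analyticity of the R-transform $R(w) = G^{-1}(w) - 1/w$.  `free_cumulants()`
therefore evaluates $R$ on the circle $|w| = 0.8\,r_c$ by Newton
continuation of $G^{-1}$ (closed-form $G$ and $G'$) and reads all Taylor
coefficients off one FFT.  The absolute error per coefficient is
$\sim \epsilon_{\text{mach}}\max|R|\,r^{-(n-1)}$, far below
$|\kappa_n|$; against exact rational arithmetic the relative error at
order 80 is $\approx 10^{-7}$, where the recursion has no correct digits.

## Optimal preprocessing

For the quartic family the effective pairwise coupling that replaces $Y$ is

$$J(Y) \;=\; \mu\sqrt{\lambda}\,Y \;-\; \gamma\lambda\,Y^{2}
\;+\; \gamma\sqrt{\lambda}\,Y^{3},$$

which reduces to $\sqrt\lambda\,Y$ in the Wigner case, and for the pure
sextic potential $J_6(x)=\xi\sqrt{\lambda}x^{5}-\xi\lambda x^{4}-\xi\lambda
x^{2}$ (the sextic coefficient table is flagged as reconstructed in
`j_coefficients()`; the absent $x^3$ term follows the source).  The
coefficients live in one function so a correction touches a single table.
At $\mu=0$, $J(x) = \gamma\sqrt\lambda\,x^2(x-\sqrt\lambda)$ is nonpositive
on the noise bulk whenever $\sqrt\lambda > 2a$, while the signal outlier
$z^{*}>\sqrt\lambda$ maps to the positive axis: the preprocessing "cleans"
the spectrum, `run_spectral_demo()` reproduces this.

We cross-checked the coefficient table by expanding the model's
Hamiltonian to quadratic order with order parameters fixed at their
Bayes-symmetric values: candidate extra linear terms (from the
$\mathrm{Tr}(ZAZA)$ and $\mathrm{Tr}(ZA^3)$ contributions) cancel exactly,
leaving the three-term polynomial above.

Inside the iterative algorithms $J(Y)u$ is always computed with $K$
matrix–vector products (`apply_poly_matvec()`); the materialized matrix
polynomial (`apply_preprocessing()`) exists for moderate-$N$ spectral
diagnostics only.

## BAMP and its multistage state evolution

The estimator is the AMP recursion
$f^t = J(Y)u^t - \sum_{i\le t} c_{t,i}u^i$,
$u^{t+1} = g_{t+1}(f^t)$ with the single-iterate posterior-mean denoiser
for the effective channel $F_t = \mu_t X^{*} + W_t$.  The Onsager
coefficients $c_{t,i}$, the signal strengths $\mu_t$ and the noise
covariance $\Sigma$ cannot be read from a single-matrix state evolution
because $J(Y)u^t$ does not split into signal plus rotationally invariant
noise.  The package implements the auxiliary-AMP construction:

1. each main iteration is unrolled into $K$ steps of an AMP on the noise
   matrix alone, $\tilde z^s = Z\tilde u^s - \sum_i \bar b_{s,i}\tilde u^i$,
   whose iterates reconstruct the powers
   $\tilde u^{K(t-1)+\ell} \approx Y^{\ell-1}u^t$ through the splitting
   $Y^k u^t = \tfrac{\sqrt\lambda}{N}X^{*}\langle X^{*}, Y^{k-1}u^t\rangle
   + Z\,Y^{k-1}u^t$;
2. the auxiliary AMP is a standard rotationally-invariant AMP, so its
   Onsager row is $\bar b_{s,\cdot} = [\sum_{j\ge1}\kappa_{j+1}\Phi^j]_{s,\cdot}$
   and its noise vector is Gaussian with covariance
   $S = \sum_{j\ge0}\kappa_{j+2}\sum_{i+k=j}\Phi^i\Delta(\Phi^{\mathsf T})^k$,
   with $\Phi$ the mean-derivative matrix and $\Delta$ the Gram matrix of
   the $\tilde u$'s;
3. expanding $J(Y)u^t$ over the atoms
   $\{X^{*}, u^1,\dots,u^t, \tilde z^1,\dots\}$ and collecting coefficients
   yields $c_{t,i}$ (on past iterates), $\mu_t$ (on the signal) and $W_t$
   (the Gaussian remainder).

Every scalar expectation in the recursion (overlaps, cross-moments,
average derivatives) is computed by Gauss–Hermite quadrature over the
limiting scalar law (151 nodes for 1-D, 61 for the bivariate
cross-moments; the GOE fixed point agrees with an independent
`integrate()`-based oracle to $10^{-9}$ at these settings).  The engine
grows all matrices row by row, so a $T$-iteration quartic run costs
$O((KT)^4)$ scalar work — seconds at the defaults.

The same engine drives the baselines by setting $J(Y) = Y$:
the rotationally-invariant AMP with single-iterate posterior mean, the
full-memory posterior-mean AMP (its conditional mean depends on
$f^1..f^t$ only through $\mu^{\mathsf T}\Sigma^{-1}f$, so it reduces to a
scalar channel), and AMP-AP, which alternates $K-1$ identity denoisers
with one full-memory posterior mean per batch and thus reassembles
$J(Y)u^t$ without ever being told its coefficients.  For a quadratic
potential ($K = 1$) the batches are degenerate — there are no identity
steps to aggregate — and AMP-AP is defined as the plain single-iterate
AMP.  (Conditioning a $K=1$ batch on *all* past iterates instead would
only retain the $O(\epsilon^2)$ initialization side information; that
behaviour belongs to the full-memory baseline, where it is tested
explicitly.)

### Validation chain

Because the Onsager formulas are easy to get subtly wrong, the engine is
validated from five independent directions: (i) on GOE noise the whole
construction collapses ($K=1$, $\kappa_2$ only) onto the classical scalar
recursion $m_{t+1} = \mathbb E[X\tanh(\lambda m_t + \sqrt{\lambda m_t}G)]$,
matched to $10^{-9}$; (ii) the covariance formula was checked against
Monte Carlo on a pure-noise linear-denoiser chain, which exercises deep
cumulants with no priors involved; (iii) the $t=1$ read-off
$(\mu_1, c_{1,1}, \Sigma_{11})$ matches a model-free least-squares
regression of $J(Y)u^1$ on $(X^{*}, u^1)$ at $N=4000$; (iv) the empirical
auxiliary AMP satisfies the power-matching condition
$\|\tilde u^{K(t-1)+\ell} - Y^{\ell-1}u^t\|^2/N < 10^{-2}$ at $N = 2000$
(`auxiliary_amp()`); (v) residuals $f^t - \mu_t X^{*}$ pass moment-based
Gaussianity checks, and fail them when the Onsager corrections are zeroed
(`gaussianity_diagnostic()`).

### Initialization and stability

All algorithms start from $u^1 = \epsilon X^{*} + \sqrt{1-\epsilon^2}\,g$,
the informative initialization the theory assumes.  The default is
$\epsilon = 0.8$.  This choice matters: the BAMP state evolution has a
basin structure, and from small $\epsilon$ it flows to the uninformative
fixed point (MSE $1/2$) even at SNRs where an informative fixed point
exists.  At quartic $\mu=0$, $\lambda=5$, the informative fixed point
(MSE $0.0262$) is reached from $\epsilon \gtrsim 0.7$ in about ten
iterations, and AMP-AP — which converges there from $\epsilon = 0.3$ —
reaches the *same* value, identifying it as the Bayes fixed point.  Below
$\lambda \approx 3.5$ the multistage state evolution loses the informative
fixed point altogether in this construction: the effective noise variance
creeps upward iteration by iteration.  This mirrors the known behaviour of
the algorithm — the auxiliary construction multiplies the number of
iterations and amplifies perturbations, the state evolution detaches from
the Bayes prediction as the SNR decreases, and finite-$N$ runs at low SNR
must be discarded when they fail to reach the fixed point.  AMP-AP and the
full-memory baseline remain stable in that regime and are the recommended
tools there.

Two further numerical choices: the full-memory channel inverts
$\Sigma$ by truncated eigendecomposition (relative cutoff $10^{-10}$),
because flooring tiny eigenvalues would keep collinear directions and
inflate the effective SNR without bound after convergence; and state
evolutions stop when successive MSE values differ by less than $10^{-7}$
(identity steps of the alternating schedule are skipped by the test), with
a cap of 30 iterations.

## Experiments

`run_phase_diagram()` sweeps an SNR grid, computing each algorithm's state
evolution once per $\lambda$ and running independent trials through it;
trials whose final MSE is not finite or exceeds $0.45$ are flagged,
counted and excluded from the aggregates, never silently dropped — the
same discard rule used at low SNR in the original experiments.  Matrix MSE
is always $\|X^{*}X^{*\mathsf T} - \hat u\hat u^{\mathsf T}\|_F^2/(2N^2)$,
evaluated through inner products.  Defaults are the desk scale $n = 2000$
with 10 trials per point (the full-scale protocol is $N = 8000$ with 50
trials; it runs unchanged, just longer), and the acceptance-style checks
in the test suite compare empirical means with state-evolution predictions
at three Monte-Carlo standard errors.  `run_universality()` repeats a
configuration with the Hadamard–Walsh eigenbasis and reports per-$\lambda$
differences with standard errors.

## Known limitations

* The replica variational formula for the mutual information is not
  implemented; the Bayes-optimal error is represented operationally by the
  BAMP/AMP-AP state-evolution fixed point.
* Learning the preprocessing coefficients from data is exposed only as
  `custom_preprocess()`; no learning procedure is shipped.
* Rank-one spikes, symmetric even potentials, and real symmetric matrices
  only; no complex Hermitian ensembles, no multi-cut equilibrium measures.
* BAMP's multistage state evolution is numerically fragile at low SNR (see
  above); this is a property of the construction, not a bug the package
  hides — the diagnostics expose it.
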