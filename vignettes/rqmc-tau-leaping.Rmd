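---
title: "Randomised quasi-Monte Carlo for tau-leaping: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Randomised quasi-Monte Carlo for tau-leaping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rqmcleap)
```

## The problem

Stochastic models of well-mixed chemical kinetics describe copy numbers
$X(t) \in \mathbb{N}^n$ of $n$ species coupled by $K$ reaction channels.
Channel $k$ is specified by reactant and product stoichiometries
$\alpha_{\cdot k}, \beta_{\cdot k}$ and a rate constant $c_k$; its net effect
is the stoichiometric vector $\zeta_k = \beta_{\cdot k} - \alpha_{\cdot k}$,
and its propensity under combinatorial mass action is
$$ a_k(X) = c_k \prod_i \binom{X_i}{\alpha_{ik}}, $$
the rate constant times the number of distinct reactant combinations (zero
when reactants are insufficient). Summary statistics $E[g(X(T))]$ are
usually estimated by Monte Carlo over simulated sample paths, with the
familiar $O(N^{-1/2})$ decay of the statistical error in the number of
paths $N$.

This package studies what happens when the pseudo-random input stream of a
*fixed-step* path simulator is replaced by a randomised low-discrepancy
stream — randomised quasi-Monte Carlo (RQMC) — and provides everything
needed to reproduce the characteristic convergence-rate behaviour: the
simulators, the point-set machinery, the estimators, three standard test
systems, and a pure-quadrature testbed that isolates the mechanism behind
the observed rate transitions.

## The two simulators

Both simulators advance on the fixed grid $t_j = j\tau$ up to $T$
(`ceiling(T / tau)` steps; a non-divisible final step is truncated so the
path ends at $T$ exactly — all shipped experiments use divisible horizons,
but the truncated branch is tested).

**Tau-leaping** fires each channel a Poisson number of times per step,
$$ X(t+\tau) = X(t) + \sum_k p_k\, \zeta_k, \qquad
   p_k \sim \mathrm{Pois}\!\big(a_k(X(t))\,\tau\big), $$
keeping the state integer-valued.

**Chemical Langevin (Euler–Maruyama)** replaces the Poisson increments by
moment-matched Gaussians,
$$ X(t+\tau) = X(t) + \sum_k \big[a_k \tau + \sqrt{a_k \tau}\, Z_k\big] \zeta_k,
   \qquad Z_k \sim \mathcal N(0,1), $$
with a real-valued state. With all inputs at their median ($Z_k = 0$) the
step degenerates to the explicit Euler step of the deterministic reaction
rate equations.

The crucial implementation detail is the *coupling*: both simulators draw
their randomness through inverse-transform sampling from one uniform
stream. Step $j$, channel $k$ consumes the stream coordinate at flat
position $(j-1)K + k$, so a path is a deterministic function of one point
$u \in [0,1)^s$ with
$$ s = K \lceil T/\tau \rceil . $$
This a-priori fixed dimension is what makes fixed-step simulators QMC-able
at all, in contrast to exact event-driven simulation whose dimension is
unbounded. The Poisson quantile is `qpois` (the exact smallest-$q$ inverse
CDF, stable far beyond the propensities arising here); the normal quantile
is `qnorm`.

## Point sets and their randomisation

`pseudo_points()` is the i.i.d. baseline. `sobol_points()` generates the
first $N$ points of a Sobol' sequence — a base-2 digital net, built from
the published Joe–Kuo direction numbers for up to 160 dimensions — and
randomises them with a linear matrix scramble (a random lower-triangular
bit matrix with unit diagonal applied to the digit vector of every
coordinate) followed by a random digital shift (XOR with a random digit
vector). The scramble and shift preserve the net's equidistribution while
making every point marginally uniform, so the RQMC estimator is unbiased
and its spread across independent randomisations is a real variance.

Design notes:

* All 32 output digits are scrambled; coordinates are returned as
  `digits / 2^32`, so values lie in $[0, 1-2^{-32}]$ and the half-open
  $[0,1)$ contract needs no clamping.
* A full $s$-dimensional set must be requested in one call; concatenating
  independent one-dimensional sets destroys the joint net structure (the
  test suite checks the joint 2-D box-count property that gluing would
  break).
* Power-of-two counts preserve the balance properties; other counts are
  allowed with a warning.
* The randomisation seed is consumed through R's RNG, so everything is
  reproducible from a single integer seed.

## Estimators

One randomisation of an $N$-point set yields the estimate
$I_N^{(m)} = N^{-1}\sum_i g(\hat X^{(i,m)}(T))$. Over $M$ independent
randomisations, `rqmc_estimate()` pools
$$ I_{M} = \frac1M \sum_m I_N^{(m)}, \qquad
   \widehat{\mathbb V}[I_M] = \frac{1}{M(M-1)} \sum_m \big(I_N^{(m)} - I_M\big)^2 , $$
and reports $\mathrm{RMSE} = \widehat{\mathbb V}[I_M]^{1/2}$. Because each
randomisation is unbiased, the statistical error *is* the mean squared
error; no reference truth is subtracted even where one is known. The MC
comparison arm uses $MN$ pseudo-random paths partitioned into $M$ batches
of $N$ and the identical formulas, so both arms consume the same number of
sample points.

Defaults follow the experimental protocol throughout: $M = 32$ for
reaction networks and $M = 128$ for the quadrature testbed.

`convergence_study()` and `quad_experiment()` sweep $N$ over powers of two
and fit the exponent $\nu$ in $\mathrm{RMSE} \sim C N^{-\nu}$ by unweighted
least squares on the $\log_2$–$\log_2$ table. The fit range is `"full"` by
default; `"upper"` (the upper half of the sizes) is used for claims about
the *limiting* large-$N$ rate. `local_slopes()` and `transition_size()`
locate the point where the fast small-$N$ regime gives way to the slow
MC-like regime, defined as the end of the first sliding window (3 sizes by
default) whose fitted local exponent drops below 0.75 — halfway between
the fast $N^{-1}$ and slow $N^{-1/2}$ regimes.

### Stabilising the variance estimate

For integrands that the scrambled net integrates *almost exactly* — most
prominently the additive quadrature family below, which is linear in each
coordinate — the pooled variance at large $N$ is produced by rare digital
events: a scramble row acting on the sub-resolution digits is all-zero
with probability $2^{-m}$ for $N = 2^m$. The expected mean squared error
still decays like $N^{-3}$, but a single batch of $M$ randomisations
estimates it with heavy skew, occasionally as exactly zero. Both study
functions therefore take a `reps` argument that averages the *squared*
RMSE over independent repetitions of the whole $M$-randomisation protocol
before the log-log fit; exact-zero entries, which carry no log-scale
information, are dropped from fits. The estimator itself is never touched.

## Built-in test systems

* **`birth_death`** — one species, degradation and autocatalytic birth at
  equal rate $c$. Mean stays at $X(0)$; variance grows as $2ctX(0)$ — for
  the underlying Markov chain and for both discretisations, which makes it
  the cleanest testbed. The scale parameter $\varepsilon$ sets
  $X(0) = \varepsilon^{-1}$; passing $c = 10\varepsilon$ instead of fixed
  $c$ keeps per-step propensities flat while copy numbers grow, which is
  how the package separates "closeness to the diffusion limit" from "copy
  number scale" as candidate drivers of the rate transition.
* **`isomerisation`** — a closed two-species system started in its
  equilibrium proportions; $X_1 + X_2$ is conserved exactly along every
  path, so the estimator spreads of the two species coincide at every $N$
  (the second species is slaved to the first, no matter how large its copy
  number).
* **`schlogl`** — the bistable Schlögl system with its standard
  parameterisation ($c_1 = 3\cdot10^{-7}$, $c_2 = 10^{-4}$,
  $c_3 = 10^{-3}$, $c_4 = 3.5$, buffers $S_2 = 10^5$ and $S_3 = 2\cdot10^5$,
  $X_1(0) = 250$), simulated with $\tau = 0.4$ to $T = 4$ — a 40-dimensional
  problem and a nonlinear stress test.

The buffer species of the Schlögl system are modelled as *frozen*: they
enter propensities at a fixed copy number and are never updated. This
matches the "constant and large" reservoir description and keeps the state
two-dimensional in effect. Tau-leap states that would go negative are
clamped to zero after the update (policy `"clamp"`, the default; `"error"`
aborts instead). The clamp only matters for the Schlögl runs; for the
monomolecular systems negative excursions are effectively impossible at
the shipped parameters. CLE states are allowed to go negative — standard
Euler–Maruyama practice — with negative propensities clamped to zero under
the square root only; propensities on real states use the polynomial
extension of the falling factorials (the natural continuation of the
combinatorial convention; a plain power-law variant would differ only at
low copy numbers).

## The quadrature testbed

Two families on $[0,1)^s$, both with integral 0 and variance 1 for every
$s$:
$$ f_{\mathrm{add}}(x) = \sqrt{12/s} \sum_i (x_i - \tfrac12), \qquad
   f_{\mathrm{prod}}(x) = \sqrt{12^s} \prod_i (x_i - \tfrac12). $$
Default dimensions are 10 (additive) and 3 (product), the sizes used in
the shipped studies. Two transformations inject the discreteness of
integer-valued simulation into these smooth integrands:

* `input_floor`: $f(\varepsilon \lfloor x/\varepsilon \rfloor)$ — quantises
  the *inputs*, producing discontinuities parallel to the coordinate axes;
* `output_floor`: $\varepsilon \lfloor f(x)/\varepsilon \rfloor$ —
  quantises the *outputs*, producing discontinuities that do not align
  with the axes. The mathematical floor is used, so negative values
  quantise downward; a consequence worth knowing is that for
  $\varepsilon \ge 2\sup|f|$ the transform collapses $f$ to the two levels
  $0$ and $-\varepsilon$ (not to the zero function).

The observed regimes, reproduced by the test suite: untransformed
integrands converge at $\nu \approx 3/2$ under RQMC regardless of $s$;
axis-aligned quantisation degrades the limiting rate to $\nu \approx 1$;
non-aligned quantisation degrades it all the way to the MC rate
$\nu \approx 1/2$, because a digital net equidistributes with respect to
axis-aligned boxes only. `mse_decomposition()` splits
$f_\varepsilon = f + (f_\varepsilon - f)$ into its continuous part and the
discontinuity residual (bounded by $\varepsilon$ for `output_floor`),
integrates both with shared point sets, and reports the switch point where
the residual's error overtakes — the scale $N = O(\varepsilon^{-1})$ at
which fast convergence stalls. This is the quantitative explanation for
why tau-leaping loses its RQMC advantage beyond a copy-number-dependent
$N$ while the continuous CLE discretisation keeps it: the discrete state
space plays the role of an output quantisation whose $\varepsilon$ is set
by the copy-number scale.

One practical caveat discovered while building the testbed: a *dyadic*
$\varepsilon$ (a power of $1/2$) aligns the input quantisation exactly
with the net's dyadic strata, and the transformed additive function is
then integrated exactly for $N \ge \varepsilon^{-1}$ per coordinate. The
shipped transformed studies use non-dyadic $\varepsilon$ (e.g. 0.1), which
is also what a generic discontinuity scale looks like.

## Problem sizes and numerical choices

The shipped studies run at desk scale, chosen so the full test suite and
the acceptance script each finish in minutes on one core while every
fitted exponent is stable to well within the tolerances asserted:

* reaction-network studies: $N = 2^4..2^{12}$ (transition studies
  $2^4..2^{11}$ with 3 pooled repetitions), $M = 32$;
* quadrature studies: $N = 2^4..2^{13}$ or $2^{12}$, $M = 128$, 3 pooled
  repetitions;
* the Schlögl exponent is reported as the median over 3 meta-seeds.

Other choices a maintainer would want stated: the moment oracle for the
test functions uses a midpoint rule — a full tensor grid up to $s = 2$, and
for larger $s$ the same per-axis rule combined through the additive/product
structure (pure quadrature either way), which reaches $10^{-6}$ accuracy
where a naive $10^6$-point grid in three dimensions would not; seeds spawn
deterministically from one meta-seed via R's RNG, and every exported
generator takes an explicit seed; `ceiling(T/\tau)` is computed with a
$10^{-9}$ relative guard so ratios like $1.6/0.2$ do not gain a spurious
step; CSV output is pinned to 17 significant digits so runs diff exactly
across platforms.

## What the synthetic experiments do and do not show

Everything here is self-contained simulation: the generators *are* the
study conditions, and the test systems are chosen so key moments are known
exactly. Passing tests therefore demonstrate correctness of the machinery
and reproducibility of the convergence phenomenology — they do not by
themselves predict the RQMC gain for an arbitrary biological network,
which depends on how the statistic of interest decomposes into coarse
continuous and fine discrete contributions (and on the effective dimension
of the integrand). The Schlögl study is the cautionary example: bistable,
nonlinear, 40-dimensional, where RQMC still beats MC by a constant but the
exponent improves only to about 0.55.

## Known limitations

* Fixed step only: no adaptive $\tau$ selection, no implicit tau-leaping,
  no exact event-driven simulation.
* The negative-population clamp is a plain post-update projection; more
  refined treatments exist and would change Schlögl paths slightly (the
  bias, not the convergence-rate surface studied here).
* Direction numbers ship for 160 dimensions; longer horizons or larger
  networks need a larger table.
* No Brownian-bridge or PCA-style reordering of the input stream; the
  first coordinates simply drive the first time steps.
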