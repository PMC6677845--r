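# rqmcleap

Randomised quasi-Monte Carlo (RQMC) estimation for fixed-step tau-leaping
and chemical Langevin simulation of well-mixed chemical reaction networks.

Monte Carlo estimation of a summary statistic `E[g(X(T))]` from simulated
sample paths converges at the familiar `O(N^-1/2)` rate in the number of
paths `N`. A fixed-step path simulator, however, consumes an a-priori known
number of uniform variates per path — `K·⌈T/τ⌉` for `K` reaction channels
stepped by `τ` up to time `T` — so its pseudo-random input stream can be
replaced by a randomised low-discrepancy stream. This package implements
that replacement end to end and the convergence-rate analysis around it:

* **Networks** (`reaction_network()`, `builtin_model()`): combinatorial
  mass-action propensities `a_k(X) = c_k ∏_i C(X_i, α_ik)`, frozen buffer
  species, and three standard test systems (linear birth–death, closed
  reversible isomerisation, the bistable Schlögl system).
* **Point sets** (`sobol_points()`, `pseudo_points()`): Sobol' digital nets
  (Joe–Kuo direction numbers, up to 160 dimensions) randomised by a linear
  matrix scramble plus digital shift, leaving every point marginally
  uniform on `[0,1)^s`.
* **Simulators** (`tau_leap_path()`, `cle_em_path()`,
  `simulate_final_states()`): Poisson tau-leaping
  `X(t+τ) = X(t) + Σ_k Pois(a_k τ) ζ_k` and the Euler–Maruyama chemical
  Langevin step `X(t+τ) = X(t) + Σ_k [a_k τ + √(a_k τ) Z_k] ζ_k`, both
  coupled to the input stream by inverse-transform sampling (`qpois` /
  `qnorm` quantiles; stream coordinate `(j-1)K + k` drives step `j`,
  channel `k`).
* **Estimators** (`rqmc_estimate()`, `run_experiment()`,
  `convergence_study()`): `M` independent randomisations pooled into an
  unbiased estimate with the variance estimator
  `σ²_M = Σ_m (I_N^(m) − I_M)² / (M(M−1))`, RMSE = `√σ²_M`, and log2–log2
  least-squares fits of the convergence exponent `ν` in `RMSE ~ C·N^−ν`,
  plus local-slope transition detection.
* **Quadrature testbed** (`test_function()`, `quad_experiment()`,
  `mse_decomposition()`): additive and product test functions on `[0,1)^s`
  (integral 0, variance 1 for every `s`) with input- and output-floor
  discontinuity transformations that replicate — and explain — the rate
  transitions seen for the discrete simulator.

The methods vignette (`vignettes/rqmc-tau-leaping.Rmd`) documents the
models, the estimator protocol, all tunable parameters and the numerical
design choices.

## Worked example

RMSE convergence of the mean S1 copy number in the Schlögl system under
RQMC tau-leaping:

```r
library(rqmcleap)

model <- builtin_model("schlogl")
model$network
#> Reaction network: 3 species, 4 reaction channels
#>   R1: 2 S1 + S2 -> 3 S1   (c = 3e-07)
#>   R2: 3 S1 -> 2 S1 + S2   (c = 0.0001)
#>   R3: S3 -> S1   (c = 0.001)
#>   R4: S1 -> S3   (c = 3.5)
#>   frozen: S2 = 1e+05, S3 = 2e+05

cfg <- simulation_config(tau = 0.4, T = 4)   # 10 steps, dimension 4*10 = 40
study <- convergence_study(model$network, model$state, cfg,
                           g = observable("S1"),
                           sample_sizes = 2^(4:10), M = 32,
                           points = "sobol", seed = 1)
study
#> Convergence study (tau_leap, sobol points, M = 32):
#>     N      rmse estimate
#>    16 3.9535828 303.8340
#>    32 2.3160342 307.4160
#>    64 2.0996599 312.1289
#>   128 1.4852238 306.6770
#>   256 1.1875523 306.7043
#>   512 0.6265864 307.3697
#>  1024 0.4392227 307.0408
#> fitted exponent nu = 0.504 (RMSE ~ N^-nu, fit over N = 16..1024)
```

Each row pools 32 independently scrambled Sobol' sets of `N` points, one
tau-leap path per point; `estimate` is the pooled mean S1 copy number at
`T = 4` (the system starts at 250 between its two stable states) and
`rmse` its estimated statistical error. The same call with
`points = "pseudo"` runs the fair MC comparison (same `32·N` paths,
identical estimator): at `N = 1024` the MC arm's RMSE is 1.03 against
0.44 for RQMC — the low-discrepancy stream wins by a constant factor even
in this 40-dimensional bistable problem, while the exponent stays close to
the MC value of 1/2. On the easy birth–death system the same experiment
gives `ν ≈ 1` for RQMC on the chemical Langevin discretisation, and a
copy-number-dependent transition from `ν ≈ 1` back to `ν ≈ 1/2` for
tau-leaping; the quadrature testbed shows why (see the vignette).

A command-line wrapper with the same functionality is installed under
`inst/cli/rqmcleap`:

```sh
rqmcleap converge --model schlogl --tau 0.4 --T 4 \
    --N 16 --N 32 --N 64 --M 32 --seed 1 --out schlogl.csv
rqmcleap simulate --model birth_death --tau 0.2 --T 1.6 --out traj.csv
rqmcleap quad --family additive --transform output_floor --epsilon 0.5 --out quad.csv
rqmcleap reproduce fig13 --seed 1 --out fig13/
```

Experiments can also be described by a YAML config (`--config file.yaml`;
schema in `?parse_config`). Results are CSV (columns `N, rmse, estimate,
method, points, model, M, seed`; trajectories `time` plus one column per
species), written with 17 significant digits so repeated runs are
byte-identical.

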