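test_that("poisson_quantile matches brute-force CDF summation", {
  expect_equal(poisson_quantile(0.7, 0), 0)
  expect_equal(poisson_quantile(0.5, 1), 1)  # CDF(0) = e^-1 < 0.5
  expect_equal(poisson_quantile(0.1, 2), 0)  # CDF(0) = e^-2 >= 0.1
  u_grid <- seq(0.005, 0.995, by = 0.015)
  for (lambda in c(0.5, 1, 2, 5, 50)) {
    expect_equal(poisson_quantile(u_grid, lambda),
                 vapply(u_grid, oracle_poisson_quantile, numeric(1), lambda))
  }
  expect_error(poisson_quantile(1, 3), "\\[0, 1\\)")
  expect_error(poisson_quantile(0.5, -1), "non-negative")
})

test_that("poisson_quantile is stable and consistent at large means", {
  lam <- 1e4
  u <- seq(0.01, 0.99, by = 0.01)
  q <- poisson_quantile(u, lam)
  expect_true(all(abs(q - lam) < 4 * sqrt(lam)))
  expect_true(all(diff(q) >= 0))
})

test_that("poisson_quantile over stratified uniforms reproduces the pmf", {
  n <- 1e5
  u <- (seq_len(n) - 0.5) / n
  for (lambda in c(0.5, 5, 50)) {
    q <- poisson_quantile(u, lambda)
    kmax <- max(q)
    counts <- tabulate(q + 1, nbins = kmax + 1)
    expected <- n * stats::dpois(0:kmax, lambda)
    # stratified inputs make the histogram essentially exact
    expect_true(all(abs(counts - expected) <= 1.5))
  }
})

test_that("normal_quantile round-trips through the normal CDF", {
  expect_identical(normal_quantile(0.5), 0)
  expect_equal(normal_quantile(0.975), 1.959964, tolerance = 1e-6)
  u <- c(1e-12, 1e-6, seq(0.001, 0.999, by = 0.007), 1 - 1e-6, 1 - 1e-12)
  expect_true(all(abs(stats::pnorm(normal_quantile(u)) - u) < 1e-9))
  expect_error(normal_quantile(0), "strictly inside")
  expect_error(normal_quantile(1), "strictly inside")
})

test_that("tau-leap paths follow the inverse-transform update rule", {
  bd <- builtin_model("birth_death", list(epsilon = 0.1, c = 1))
  cfg1 <- simulation_config(0.2, 0.2)
  # both channels have a*tau = 2; u = 0.5 maps to 2 firings each, net zero
  tr <- tau_leap_path(bd$network, bd$state, cfg1, c(0.5, 0.5))
  expect_equal(unname(tr$states[2, 1]), 10)

  # uniforms below exp(-max a_k tau) never fire anything
  cfg <- simulation_config(0.2, 1.6)
  u0 <- rep(exp(-2) / 2, 16)
  tr0 <- tau_leap_path(bd$network, bd$state, cfg, u0)
  expect_true(all(tr0$states == 10))
})

test_that("tau-leap trajectories match an R-level oracle, incl. truncated step", {
  sch <- builtin_model("schlogl")
  set.seed(31)
  for (Ttau in list(c(1.2, 0.4), c(1.0, 0.3))) {
    T <- Ttau[1]; tau <- Ttau[2]
    cfg <- simulation_config(tau, T)
    steps <- ceiling(T / tau - 1e-9)
    u <- stats::runif(4 * steps)
    tr <- tau_leap_path(sch$network, sch$state, cfg, u)
    expect_equal(tr$times[length(tr$times)], T)
    expect_equal(unname(tr$states[nrow(tr$states), ]),
                 unname(oracle_tau_leap(sch$network, sch$state$copy_numbers,
                                        tau, T, u)))
  }
})

test_that("identical streams give bit-identical trajectories", {
  sch <- builtin_model("schlogl")
  cfg <- simulation_config(0.4, 4)
  u <- sobol_points(1, 40, seed = 8)$values[1, ]
  t1 <- tau_leap_path(sch$network, sch$state, cfg, u)
  t2 <- tau_leap_path(sch$network, sch$state, cfg, u)
  expect_identical(t1$states, t2$states)
})

test_that("stream length is checked as a hard error", {
  bd <- builtin_model("birth_death")
  cfg <- simulation_config(0.2, 1.6)
  expect_error(tau_leap_path(bd$network, bd$state, cfg, runif(15)),
               "expected 16")
  expect_error(cle_em_path(bd$network, bd$state, cfg, runif(17)),
               "expected 16")
})

test_that("tau-leap conserves the closed isomerisation total exactly", {
  iso <- builtin_model("isomerisation")
  cfg <- simulation_config(0.2, 1.6)
  n0 <- sum(iso$state$copy_numbers)
  for (sd in 1:3) {
    u <- sobol_points(1, 16, seed = sd)$values[1, ]
    tr <- tau_leap_path(iso$network, iso$state, cfg, u)
    expect_identical(unname(rowSums(tr$states)), rep(n0, nrow(tr$states)))
  }
})

test_that("CLE-EM at u = 1/2 reduces to the explicit Euler rate equations", {
  iso <- builtin_model("isomerisation")
  cfg <- simulation_config(0.2, 0.4, "cle_em")
  tr <- cle_em_path(iso$network, iso$state, cfg, rep(0.5, 4))
  x <- iso$state$copy_numbers
  for (row in 2:3) {
    a <- c(1 * x[1], 1e-4 * x[2])
    x <- x + 0.2 * drop(iso$network$zeta %*% a)
    expect_equal(unname(tr$states[row, ]), unname(x))
  }
})

test_that("CLE-EM increments follow drift plus sqrt(a tau) noise", {
  bd <- builtin_model("birth_death", list(epsilon = 1e-2, c = 1))
  cfg <- simulation_config(0.2, 0.2, "cle_em")
  # z = 1 on the birth channel: X = 100 + sqrt(100 * 0.2) = 100 + sqrt(20)
  tr <- cle_em_path(bd$network, bd$state, cfg, c(0.5, stats::pnorm(1)))
  expect_equal(unname(tr$states[2, 1]), 100 + sqrt(20))
  # equal z on both channels cancels drift and noise exactly
  z <- stats::pnorm(0.7)
  tr2 <- cle_em_path(bd$network, bd$state, cfg, c(z, z))
  expect_equal(unname(tr2$states[2, 1]), 100)
})

test_that("both simulators reproduce the birth-death moment identities", {
  # E[X(T)] = X(0) and V[X(T)] = 2 c T X(0) hold exactly for this system,
  # for the discrete tau-leap scheme and the CLE discretisation alike
  bd <- builtin_model("birth_death", list(epsilon = 1e-3, c = 1))
  n <- 1e4
  for (method in c("tau_leap", "cle_em")) {
    cfg <- simulation_config(0.2, 1.6, method)
    r <- run_experiment(bd$network, bd$state, cfg, observable("S1"),
                        N = n / 4, M = 4, points = "pseudo", seed = 99)
    expect_lt(abs(r$pooled_estimate - 1000), 5 * sqrt(3200 / n))
  }
})

test_that("final_value reads observables off the trajectory end", {
  sch <- builtin_model("schlogl")
  cfg <- simulation_config(0.4, 4)
  u <- sobol_points(1, 40, seed = 3)$values[1, ]
  tr <- tau_leap_path(sch$network, sch$state, cfg, u)
  xT <- tr$states[nrow(tr$states), "S1"]
  expect_equal(unname(final_value(tr, observable("S1"))), unname(xT))
  expect_equal(unname(final_value(tr, observable("S1", 2))), unname(xT^2))
  expect_equal(unname(final_value(tr, observable("S2"))), 1e5)
})
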