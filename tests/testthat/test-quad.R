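test_that("test functions evaluate per their closed forms", {
  for (s in c(1, 3, 10))
    expect_equal(quad_evaluate(test_function("additive", s),
                               rep(0.5, s)), 0)
  # product family near the corner (1,1): sqrt(144) * 1/4 -> 3
  p2 <- test_function("product", 2)
  x <- 1 - 1e-12
  expect_equal(quad_evaluate(p2, c(x, x)), 3, tolerance = 1e-6)
  # input quantisation: x = 0.7 with eps = 0.5 collapses to f(0.5) = 0
  spec <- test_function("additive", 1, "input_floor", epsilon = 0.5)
  expect_equal(quad_evaluate(spec, 0.7), 0)
  # output quantisation uses the mathematical floor (toward -infinity)
  spec2 <- test_function("additive", 1, "output_floor", epsilon = 0.5)
  expect_equal(quad_evaluate(spec2, 0.25),
               0.5 * floor(sqrt(12) * (-0.25) / 0.5))
  expect_error(quad_evaluate(p2, c(0.2, 1.0)), "\\[0, 1\\)")
  expect_error(quad_evaluate(p2, c(0.2, 0.3, 0.4)), "coordinates")
})

test_that("defaults and validation of the specification", {
  expect_equal(test_function("additive")$s, 10L)
  expect_equal(test_function("product")$s, 3L)
  expect_error(test_function("additive", 3, "input_floor"), "epsilon")
  expect_error(test_function("additive", 3, "input_floor", epsilon = 1.5),
               "\\(0, 1\\]")
  expect_error(test_function("additive", 3, epsilon = 0.1), "transform")
})

test_that("moment oracle confirms integral 0 and variance 1 for all s", {
  for (fam in c("additive", "product")) {
    for (s in c(1, 2, 3, 10)) {
      # the full 2-D grid needs a finer mesh to push the midpoint error
      # comfortably below the tolerance
      mom <- quad_moment_oracle(test_function(fam, s),
                                points = if (s == 2) 4e6 else 1e6)
      expect_lt(abs(mom$integral - 0), 1e-6)
      expect_lt(abs(mom$variance - 1), 1e-6)
      tm <- true_moments(test_function(fam, s))
      expect_identical(c(tm$integral, tm$variance), c(0, 1))
    }
  }
  expect_error(true_moments(test_function("additive", 2, "input_floor",
                                          epsilon = 0.5)), "untransformed")
})

test_that("sample variance of both families is 1 at large N", {
  u <- pseudo_points(1e5, 3, seed = 8)$values
  for (fam in c("additive", "product")) {
    fx <- quad_evaluate(test_function(fam, 3), u)
    expect_lt(abs(stats::var(fx) - 1), 0.05)
  }
})

test_that("input quantisation converges pointwise as eps -> 0", {
  spec0 <- test_function("additive", 2)
  x <- rbind(c(1 / 3, 2 / 7), c(0.9, 0.05))
  for (eps in 2^-(4:8)) {
    spec <- test_function("additive", 2, "input_floor", epsilon = eps)
    expect_lt(max(abs(quad_evaluate(spec, x) - quad_evaluate(spec0, x))),
              sqrt(12 / 2) * 2 * eps)
  }
})

test_that("coarse output quantisation collapses to the floor levels", {
  # with eps >= 2 sup|f| the ratio f / eps lies in (-1/2, 1/2), so the
  # mathematical floor leaves only the levels 0 (f >= 0) and -eps (f < 0)
  spec0 <- test_function("additive", 2)
  eps <- 2 * sqrt(12 * 2) / 2  # 2 * sup|f|
  spec <- test_function("additive", 2, "output_floor", epsilon = eps)
  u <- pseudo_points(500, 2, seed = 4)$values
  f0 <- quad_evaluate(spec0, u)
  fe <- quad_evaluate(spec, u)
  expect_true(all(fe %in% c(0, -eps)))
  expect_equal(fe == 0, f0 >= 0)
})

test_that("the output-floor residual is bounded by eps", {
  for (eps in c(0.1, 0.5, 2)) {
    spec <- test_function("product", 3, "output_floor", epsilon = eps)
    base <- test_function("product", 3)
    u <- pseudo_points(2000, 3, seed = 11)$values
    G <- quad_evaluate(spec, u) - quad_evaluate(base, u)
    expect_true(all(G <= 0 & G > -eps))  # floor residual in (-eps, 0]
  }
})

test_that("full scrambled nets integrate the additive family almost exactly", {
  # every digit of every coordinate deeper than the net resolution m can
  # shift the mean by at most 2^-(m+1) per coordinate, giving the bound
  # sqrt(3 s) * 2^-m on |sample mean| for the scaled additive function
  m <- 10
  for (s in c(2, 5)) {
    spec <- test_function("additive", s)
    for (sd in c(1, 2)) {
      ps <- sobol_points(2^m, s, seed = sd)
      expect_lt(abs(mean(quad_evaluate(spec, ps$values))), sqrt(3 * s) * 2^-m)
    }
  }
})

test_that("quadrature studies converge at the documented rates", {
  # MC baseline on the additive family: nu ~ 1/2
  st_mc <- quad_experiment(test_function("additive", 3), 2^(4:10), M = 32,
                           points = "pseudo", seed = 21)
  expect_lt(abs(st_mc$fitted_exponent - 0.5), 0.2)
  # RQMC: much faster than MC everywhere
  st_rq <- quad_experiment(test_function("additive", 3), 2^(4:10), M = 32,
                           points = "sobol", seed = 22)
  expect_true(all(st_rq$table$rmse < st_mc$table$rmse))
})

test_that("the MSE decomposition locates the discontinuity switch point", {
  sizes <- 2^(4:11)
  dec_big <- mse_decomposition(test_function("additive", 3, "output_floor",
                                             epsilon = 0.4),
                               sizes, M = 64, seed = 31)
  dec_small <- mse_decomposition(test_function("additive", 3, "output_floor",
                                               epsilon = 0.1),
                                 sizes, M = 64, seed = 31)
  # smaller eps pushes the switch to larger N (N = O(1/eps))
  expect_true(dec_small$switch_N >= dec_big$switch_N)
  # the large-N discontinuous MSE scales like eps^2: ratio ~ (0.1/0.4)^2
  last <- nrow(dec_big$table)
  ratio <- dec_small$table$mse_discontinuous[last] /
    dec_big$table$mse_discontinuous[last]
  expect_gt(ratio, (0.1 / 0.4)^2 / 4)
  expect_lt(ratio, (0.1 / 0.4)^2 * 4)
  expect_error(mse_decomposition(test_function("additive", 3), sizes),
               "transformed")
})
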