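#' Quadrature test-function specification
#'
#' The two standard families on the unit hypercube used to dissect RQMC
#' convergence behaviour:
#' \describe{
#'   \item{additive}{`f(x) = sqrt(12 / s) * sum_i (x_i - 1/2)` - effective
#'     dimension one; an easy integrand for digital nets.}
#'   \item{product}{`f(x) = sqrt(12^s) * prod_i (x_i - 1/2)` - a hard,
#'     fully s-dimensional integrand.}
#' }
#' Both have integral 0 and variance 1 over `[0,1)^s`, for every `s`.
#' Two discontinuity transformations emulate the integer-valued state space
#' of discrete stochastic simulation:
#' \describe{
#'   \item{input_floor}{`f_eps(x) = f(eps * floor(x / eps))` - quantises the
#'     inputs, producing axis-aligned discontinuities.}
#'   \item{output_floor}{`f_eps(x) = eps * floor(f(x) / eps)` - quantises the
#'     outputs, producing discontinuities not aligned with the axes
#'     (mathematical floor, so negative values quantise downward).}
#' }
#'
#' @param family `"additive"` or `"product"`.
#' @param s Dimension, `>= 1`. Defaults to 10 for the additive family and 3
#'   for the product family.
#' @param transform `"none"`, `"input_floor"` or `"output_floor"`.
#' @param epsilon Discontinuity scale; required for a transform, must lie in
#'   `(0, 1]` for `input_floor`.
#' @return An object of class `"test_function"`.
#' @export
test_function <- function(family = c("additive", "product"), s = NULL,
                          transform = c("none", "input_floor", "output_floor"),
                          epsilon = NULL) {
  family <- match.arg(family)
  transform <- match.arg(transform)
  if (is.null(s)) s <- if (family == "additive") 10L else 3L
  if (!is.numeric(s) || length(s) != 1 || s < 1 || s != round(s))
    stop("s must be a positive integer", call. = FALSE)
  if (transform == "none") {
    if (!is.null(epsilon))
      stop("epsilon only applies to the transformed functions", call. = FALSE)
  } else {
    if (is.null(epsilon) || !is.numeric(epsilon) || length(epsilon) != 1 ||
        epsilon <= 0)
      stop("a positive epsilon is required for transform = \"", transform,
           "\"", call. = FALSE)
    if (transform == "input_floor" && epsilon > 1)
      stop("epsilon must lie in (0, 1] for the input_floor transform",
           call. = FALSE)
  }
  structure(list(family = family, s = as.integer(s), transform = transform,
                 epsilon = epsilon),
            class = "test_function")
}

#' Evaluate a test function at points of the unit hypercube
#'
#' @param spec A [test_function()].
#' @param x A point (numeric vector of length `s`) or a matrix with `s`
#'   columns, entries in `[0, 1)`.
#' @return Numeric vector of function values, one per point.
#' @export
#' @examples
#' quad_evaluate(test_function("additive", s = 2), c(0.5, 0.5))  # 0
quad_evaluate <- function(spec, x) {
  stopifnot(inherits(spec, "test_function"))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != spec$s)
    stop("points have ", ncol(x), " coordinates, spec has s = ", spec$s,
         call. = FALSE)
  if (any(x < 0) || any(x >= 1))
    stop("points must lie in [0, 1)^s", call. = FALSE)
  if (spec$transform == "input_floor")
    x <- spec$epsilon * floor(x / spec$epsilon)
  base <- switch(spec$family,
    additive = sqrt(12 / spec$s) * rowSums(x - 0.5),
    product = sqrt(12^spec$s) * apply(x - 0.5, 1, prod))
  if (spec$transform == "output_floor")
    base <- spec$epsilon * floor(base / spec$epsilon)
  base
}

#' Integral and variance of the untransformed test functions
#'
#' Returns the analytic integral 0 and variance 1 of either family; the
#' companion [quad_moment_oracle()] recomputes both by midpoint-rule
#' quadrature without using the closed form, as an independent check. The
#' transformed functions have no closed-form moments and are handled only
#' empirically.
#'
#' @param spec A [test_function()] with `transform = "none"`.
#' @return List with `integral` and `variance`.
#' @export
true_moments <- function(spec) {
  stopifnot(inherits(spec, "test_function"))
  if (spec$transform != "none")
    stop("closed-form moments are only available for the untransformed ",
         "functions", call. = FALSE)
  list(integral = 0, variance = 1)
}

#' Brute-force midpoint-rule moments of a test function
#'
#' Midpoint-rule quadrature of `f` and `f^2` over `[0,1)^s`. For `s <= 2`
#' the full tensor grid is enumerated. For larger `s` the same midpoint rule
#' is applied per axis and combined through the additive/product structure
#' of the families (sums and products of independent coordinates), which is
#' still pure quadrature - no closed-form moment is used anywhere.
#'
#' @param spec A [test_function()] with `transform = "none"` (the
#'   transformed variants are only supported for `s <= 2`, where the full
#'   grid is feasible).
#' @param points Total number of grid points for the full-grid branch
#'   (default `1e6`), also the per-axis count for the factorised branch.
#' @return List with `integral` and `variance`.
#' @export
quad_moment_oracle <- function(spec, points = 1e6) {
  stopifnot(inherits(spec, "test_function"))
  s <- spec$s
  if (s <= 2) {
    n_axis <- floor(points^(1 / s))
    mid <- (seq_len(n_axis) - 0.5) / n_axis
    grid <- as.matrix(do.call(expand.grid, rep(list(mid), s)))
    fx <- quad_evaluate(spec, grid)
    return(list(integral = mean(fx), variance = mean(fx^2) - mean(fx)^2))
  }
  if (spec$transform != "none")
    stop("full-grid oracle for transformed functions is only feasible for ",
         "s <= 2", call. = FALSE)
  # Per-axis midpoint sums of the centred coordinate and its square,
  # combined exactly across axes by independence of the coordinates.
  mid <- (seq_len(points) - 0.5) / points
  m1 <- mean(mid - 0.5)      # per-axis first moment (midpoint rule)
  m2 <- mean((mid - 0.5)^2)  # per-axis second moment
  if (spec$family == "additive") {
    integral <- sqrt(12 / s) * s * m1
    second <- (12 / s) * (s * m2 + s * (s - 1) * m1^2)
  } else {
    integral <- sqrt(12^s) * m1^s
    second <- 12^s * m2^s
  }
  list(integral = integral, variance = second - integral^2)
}

# Shared RQMC/MC quadrature estimator: values of `f` at point-set rows.
quad_run <- function(valfun, s, N, M, points, seed) {
  seeds <- spawn_seeds(seed, M + 1L)
  vals <- matrix(NA_real_, M, N)
  if (points == "sobol") {
    for (m in seq_len(M))
      vals[m, ] <- valfun(sobol_points(N, s, seed = seeds[m])$values)
  } else {
    U <- pseudo_points(M * N, s, seed = seeds[M + 1L])$values
    vals[] <- matrix(valfun(U), M, N, byrow = TRUE)
  }
  vals
}

#' RMSE convergence study for a quadrature test function
#'
#' Estimates `int f_eps` by MC or RQMC at each sample size, with `M`
#' randomisations pooled through [rqmc_estimate()], and fits the
#' convergence-rate exponent - the quadrature analogue of
#' [convergence_study()].
#'
#' For the additive family under the linear matrix scramble the empirical
#' variance at large `N` is dominated by rare below-resolution events, so a
#' single batch of `M` randomisations estimates it with heavy skew (possibly
#' exactly zero). The `reps` argument pools the mean squared error over
#' several independent repetitions of the whole `M`-randomisation protocol,
#' which stabilises the log-log fit without touching the estimator itself.
#'
#' @param spec A [test_function()].
#' @param sample_sizes Increasing sample sizes (at least 3).
#' @param M Randomisations per size (default 128).
#' @param points `"sobol"` or `"pseudo"`.
#' @param seed Meta seed.
#' @param fit_range See [fit_rate()].
#' @param reps Independent repetitions over which the squared RMSE is
#'   averaged (default 1).
#' @return A `"convergence_study"`.
#' @export
quad_experiment <- function(spec, sample_sizes, M = 128,
                            points = c("sobol", "pseudo"), seed = 1,
                            fit_range = "full", reps = 1) {
  points <- match.arg(points)
  stopifnot(inherits(spec, "test_function"), reps >= 1)
  if (length(sample_sizes) < 3)
    stop("a convergence study needs at least 3 sample sizes", call. = FALSE)
  if (is.unsorted(sample_sizes, strictly = TRUE))
    stop("sample_sizes must be strictly increasing", call. = FALSE)
  rep_seeds <- spawn_seeds(seed, reps)
  runs <- lapply(rep_seeds, function(rs) {
    seeds <- spawn_seeds(rs, length(sample_sizes))
    lapply(seq_along(sample_sizes), function(i) {
      vals <- quad_run(function(U) quad_evaluate(spec, U), spec$s,
                       sample_sizes[i], M, points, seeds[i])
      rqmc_estimate(vals)
    })
  })
  res <- runs[[1]]
  mse <- rowMeans(vapply(runs, function(rr)
    vapply(rr, `[[`, numeric(1), "variance_of_mean"),
    numeric(length(sample_sizes))))
  tab <- data.frame(N = sample_sizes,
                    rmse = sqrt(mse),
                    estimate = rowMeans(vapply(runs, function(rr)
                      vapply(rr, `[[`, numeric(1), "pooled_estimate"),
                      numeric(length(sample_sizes)))))
  fit <- fit_rate(tab$N, tab$rmse, fit_range)
  structure(list(table = tab, fitted_exponent = fit$fitted_exponent,
                 fit_range = fit$fit_range, method = NULL, points = points,
                 M = M, seed = seed, spec = spec, results = res),
            class = "convergence_study")
}

#' Decompose the mean squared error of a discontinuous test function
#'
#' Splits `f_eps = F + G` into the continuous part `F = f` and the
#' discontinuity residual `G = f_eps - f` (bounded by `eps` for the
#' output-floor transform), integrates both with the same shared randomised
#' point sets, and reports the statistical MSE of each component per sample
#' size. The empirical switch point is the first `N` at which the
#' discontinuous component's MSE overtakes the continuous one - the scale at
#' which the fast digital-net convergence stalls.
#'
#' @param spec A [test_function()] with a transform.
#' @param sample_sizes Increasing sample sizes.
#' @param M Randomisations (default 128).
#' @param seed Meta seed.
#' @return List with `table` (data frame `N`, `mse_total`, `mse_continuous`,
#'   `mse_discontinuous`) and `switch_N` (possibly `Inf`).
#' @export
mse_decomposition <- function(spec, sample_sizes, M = 128, seed = 1) {
  stopifnot(inherits(spec, "test_function"))
  if (spec$transform == "none")
    stop("the MSE decomposition applies to the transformed functions",
         call. = FALSE)
  base <- test_function(spec$family, spec$s)
  seeds <- spawn_seeds(seed, length(sample_sizes))
  rows <- lapply(seq_along(sample_sizes), function(i) {
    N <- sample_sizes[i]
    ss <- spawn_seeds(seeds[i], M)
    tot <- cont <- disc <- matrix(NA_real_, M, N)
    for (m in seq_len(M)) {
      U <- sobol_points(N, spec$s, seed = ss[m])$values
      fe <- quad_evaluate(spec, U)
      f0 <- quad_evaluate(base, U)
      tot[m, ] <- fe
      cont[m, ] <- f0
      disc[m, ] <- fe - f0
    }
    c(N = N,
      mse_total = rqmc_estimate(tot)$variance_of_mean,
      mse_continuous = rqmc_estimate(cont)$variance_of_mean,
      mse_discontinuous = rqmc_estimate(disc)$variance_of_mean)
  })
  tab <- as.data.frame(do.call(rbind, rows))
  hit <- which(tab$mse_discontinuous > tab$mse_continuous)
  list(table = tab, switch_N = if (length(hit) == 0) Inf else tab$N[hit[1]])
}
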