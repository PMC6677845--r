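#' Plain Monte Carlo estimate
#'
#' @param values Non-empty numeric vector of sampled observable values.
#' @return Their arithmetic mean.
#' @export
mc_estimate <- function(values) {
  if (!is.numeric(values) || length(values) == 0)
    stop("values must be a non-empty numeric vector", call. = FALSE)
  mean(values)
}

#' Pool M randomisations into an RQMC estimate with error bars
#'
#' Given an `M x N` matrix whose row `m` holds the `N` observable values
#' obtained from the m-th independently randomised point set, forms the
#' per-randomisation estimates `I_N^(m)` (row means), the pooled estimate
#' (their mean), and the unbiased estimator of the variance of the pooled
#' mean, `sum_m (I_N^(m) - I)^2 / (M (M - 1))`. The reported RMSE is the
#' square root of that variance: because each randomisation is unbiased,
#' the statistical error is the whole mean squared error.
#'
#' @param per_randomisation_values `M x N` numeric matrix, `M >= 2`.
#' @return An object of class `"rqmc_result"`: list with
#'   `per_randomisation` (length `M`), `pooled_estimate`,
#'   `variance_of_mean`, `rmse`, `N`, `M`.
#' @export
#' @examples
#' rqmc_estimate(rbind(c(0, 2), c(2, 4)))  # pooled 2, variance 1
rqmc_estimate <- function(per_randomisation_values) {
  v <- per_randomisation_values
  if (!is.matrix(v) || !is.numeric(v))
    stop("expected an M x N numeric matrix", call. = FALSE)
  M <- nrow(v)
  if (M < 2)
    stop("at least M = 2 randomisations are needed to estimate the variance",
         call. = FALSE)
  I_m <- rowMeans(v)
  pooled <- mean(I_m)
  var_mean <- sum((I_m - pooled)^2) / (M * (M - 1))
  structure(list(per_randomisation = I_m, pooled_estimate = pooled,
                 variance_of_mean = var_mean, rmse = sqrt(var_mean),
                 N = ncol(v), M = M),
            class = "rqmc_result")
}

#' @export
print.rqmc_result <- function(x, ...) {
  cat(sprintf("RQMC estimate: %.6g (rmse %.3g; N = %d, M = %d)\n",
              x$pooled_estimate, x$rmse, x$N, x$M))
  invisible(x)
}

# Deterministic child seeds below 2^31 derived from one meta seed.
spawn_seeds <- function(seed, k) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)
}

#' Estimate an observable of a reaction network by MC or RQMC
#'
#' Runs `M * N` fixed-step sample paths and pools them with
#' [rqmc_estimate()]. For `points = "sobol"` each of the `M` batches is an
#' independently seeded randomised Sobol' point set of `N` points (one path
#' per point); for `points = "pseudo"` all `M * N` paths are pseudo-random
#' and partitioned into `M` batches, so both arms use the same number of
#' sample points and the identical estimator formulas - the fair comparison
#' between RQMC and standard MC.
#'
#' @param network A [reaction_network()].
#' @param state Initial [system_state()].
#' @param cfg A [simulation_config()] selecting tau-leap or CLE-EM.
#' @param g An [observable()], or a list of observables to be evaluated on
#'   the same sample paths (in which case a list of results is returned).
#' @param N Points per randomisation (powers of two recommended).
#' @param M Number of randomisations, `>= 2` (default 32).
#' @param points `"sobol"` (randomised Sobol') or `"pseudo"`.
#' @param seed Meta seed; spawns one child seed per randomisation plus an
#'   independent stream for the pseudo arm.
#' @return An `"rqmc_result"`, or a list of them when `g` is a list.
#' @export
run_experiment <- function(network, state, cfg, g = observable(), N, M = 32,
                           points = c("sobol", "pseudo"), seed = 1) {
  points <- match.arg(points)
  stopifnot(inherits(network, "reaction_network"),
            inherits(cfg, "simulation_config"))
  single <- inherits(g, "observable")
  gs <- if (single) list(g) else g
  stopifnot(all(vapply(gs, inherits, logical(1), "observable")))
  K <- length(network$reactions)
  s <- cfg$steps * K
  seeds <- spawn_seeds(seed, M + 1L)

  batch_values <- function(ps) {
    finals <- simulate_final_states(network, state, cfg, ps)
    lapply(gs, apply_observable, states = finals)
  }

  vals <- vector("list", length(gs))  # each: M x N matrix
  for (i in seq_along(gs)) vals[[i]] <- matrix(NA_real_, M, N)
  if (points == "sobol") {
    for (m in seq_len(M)) {
      bv <- batch_values(sobol_points(N, s, seed = seeds[m]))
      for (i in seq_along(gs)) vals[[i]][m, ] <- bv[[i]]
    }
  } else {
    bv <- batch_values(pseudo_points(M * N, s, seed = seeds[M + 1L]))
    for (i in seq_along(gs)) vals[[i]][] <- matrix(bv[[i]], M, N, byrow = TRUE)
  }
  res <- lapply(vals, function(v) {
    r <- rqmc_estimate(v)
    r$seed <- seed
    r$points <- points
    r$method <- cfg$method
    r
  })
  if (single) res[[1]] else res
}

#' Fit a convergence-rate exponent to an RMSE-versus-N table
#'
#' Unweighted least squares of `log2(rmse)` on `log2(N)`; the exponent `nu`
#' is minus the slope, so `rmse ~ C * N^-nu`.
#'
#' @param sample_sizes Increasing sample sizes.
#' @param rmse_values Positive RMSE values, same length.
#' @param fit_range `"full"` (all points) or `"upper"` (upper half of the
#'   sizes, the large-N limiting rate), or an integer index vector.
#' @return List with `fitted_exponent` and `fit_range` (indices used).
#' @export
fit_rate <- function(sample_sizes, rmse_values, fit_range = "full") {
  stopifnot(length(sample_sizes) == length(rmse_values))
  idx <- resolve_fit_range(fit_range, length(sample_sizes))
  if (length(idx) < 3)
    stop("rate fitting needs at least 3 points", call. = FALSE)
  # an RMSE of exactly zero means the point set integrated the function
  # exactly; such points carry no log-scale information and are dropped
  idx <- idx[rmse_values[idx] > 0]
  if (length(idx) < 3)
    stop("rate fitting needs at least 3 points with positive RMSE",
         call. = FALSE)
  fit <- stats::lm(log2(rmse_values[idx]) ~ log2(sample_sizes[idx]))
  list(fitted_exponent = -unname(stats::coef(fit)[2]), fit_range = idx)
}

resolve_fit_range <- function(fit_range, n) {
  if (is.numeric(fit_range)) return(as.integer(fit_range))
  switch(match.arg(fit_range, c("full", "upper")),
         full = seq_len(n),
         upper = seq.int(max(1L, floor(n / 2)), n))
}

#' Sliding-window local slopes of an RMSE curve
#'
#' Least-squares slope of `log2(rmse)` vs `log2(N)` over windows of
#' `window` consecutive sizes, reported at the window's last size. Used to
#' locate the transition out of the fast convergence regime.
#'
#' @inheritParams fit_rate
#' @param window Number of consecutive points per slope (default 3).
#' @return Data frame with columns `N` (window end) and `slope` (the local
#'   exponent `nu`, i.e. minus the fitted slope).
#' @export
local_slopes <- function(sample_sizes, rmse_values, window = 3) {
  stopifnot(length(sample_sizes) == length(rmse_values),
            window >= 2, length(sample_sizes) >= window)
  ends <- seq.int(window, length(sample_sizes))
  slope <- vapply(ends, function(e) {
    idx <- (e - window + 1L):e
    -unname(stats::coef(stats::lm(log2(rmse_values[idx]) ~
                                    log2(sample_sizes[idx])))[2])
  }, numeric(1))
  data.frame(N = sample_sizes[ends], slope = slope)
}

#' First sample size at which the local rate drops below a threshold
#'
#' @inheritParams local_slopes
#' @param threshold Rate threshold (default 0.75, halfway between the fast
#'   `N^-1` and slow `N^-1/2` regimes).
#' @return The first window-end `N` whose local exponent falls below
#'   `threshold`, or `Inf` if the fast regime persists over the whole table.
#' @export
transition_size <- function(sample_sizes, rmse_values, threshold = 0.75,
                            window = 3) {
  ls <- local_slopes(sample_sizes, rmse_values, window)
  hit <- which(ls$slope < threshold)
  if (length(hit) == 0) Inf else ls$N[hit[1]]
}

#' Convergence study of the RMSE as a function of N
#'
#' Runs [run_experiment()] at each sample size and fits the convergence-rate
#' exponent.
#'
#' @inheritParams run_experiment
#' @param sample_sizes Increasing vector of at least 3 sample sizes (powers
#'   of two recommended).
#' @param fit_range See [fit_rate()].
#' @param reps Independent repetitions of the whole M-randomisation protocol
#'   over which the squared RMSE is averaged (default 1); pooling stabilises
#'   the log-log fit when the variance estimate at a single `M` is noisy.
#' @return An object of class `"convergence_study"`: list with `table` (data
#'   frame `N`, `rmse`, `estimate`), `fitted_exponent`, `fit_range`,
#'   `method`, `points`, and the call parameters.
#' @export
convergence_study <- function(network, state, cfg, g = observable(),
                              sample_sizes, M = 32,
                              points = c("sobol", "pseudo"), seed = 1,
                              fit_range = "full", reps = 1) {
  points <- match.arg(points)
  if (!inherits(g, "observable"))
    stop("convergence_study takes a single observable; use run_experiment ",
         "directly for several observables on shared paths", call. = FALSE)
  if (length(sample_sizes) < 3)
    stop("a convergence study needs at least 3 sample sizes", call. = FALSE)
  if (is.unsorted(sample_sizes, strictly = TRUE))
    stop("sample_sizes must be strictly increasing", call. = FALSE)
  rep_seeds <- spawn_seeds(seed, reps)
  runs <- lapply(rep_seeds, function(rs) {
    seeds <- spawn_seeds(rs, length(sample_sizes))
    lapply(seq_along(sample_sizes), function(i) {
      run_experiment(network, state, cfg, g, N = sample_sizes[i], M = M,
                     points = points, seed = seeds[i])
    })
  })
  res <- runs[[1]]
  take <- function(field) rowMeans(vapply(runs, function(rr)
    vapply(rr, `[[`, numeric(1), field), numeric(length(sample_sizes))))
  tab <- data.frame(N = sample_sizes,
                    rmse = sqrt(take("variance_of_mean")),
                    estimate = take("pooled_estimate"))
  fit <- fit_rate(tab$N, tab$rmse, fit_range)
  structure(list(table = tab, fitted_exponent = fit$fitted_exponent,
                 fit_range = fit$fit_range, method = cfg$method,
                 points = points, M = M, seed = seed, results = res),
            class = "convergence_study")
}

#' @export
print.convergence_study <- function(x, ...) {
  cat(sprintf("Convergence study (%s, %s points, M = %d):\n",
              x$method %||% "quadrature", x$points, x$M))
  print(x$table, row.names = FALSE)
  cat(sprintf("fitted exponent nu = %.3f (RMSE ~ N^-nu, fit over N = %s)\n",
              x$fitted_exponent,
              paste(x$table$N[range(x$fit_range)], collapse = "..")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a convergence table to CSV
#'
#' Columns `N`, `rmse`, `estimate`, `method`, `points`, `M`, `seed`, with
#' numbers at 17 significant digits.
#'
#' @param study A `"convergence_study"`.
#' @param path Output file path.
#' @param model Optional model label column.
#' @return `path`, invisibly.
#' @export
write_convergence_csv <- function(study, path, model = NA_character_) {
  stopifnot(inherits(study, "convergence_study"))
  df <- cbind(study$table,
              data.frame(method = study$method %||% "quadrature",
                         points = study$points, model = model, M = study$M,
                         seed = study$seed))
  write_csv17(df, path)
}
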