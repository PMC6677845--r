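#' Poisson quantile (inverse transform)
#'
#' The smallest integer `q` with `P(Pois(mean) <= q) >= u` - the map used to
#' couple a uniform stream coordinate to a tau-leap firing count. Vectorised
#' over `u` and `mean`.
#'
#' @param u Uniform variate(s) in `[0, 1)`.
#' @param mean Poisson mean(s), `>= 0`.
#' @return Non-negative integer-valued numeric vector.
#' @export
#' @examples
#' poisson_quantile(0.5, 1)  # 1
#' poisson_quantile(0.1, 2)  # 0
poisson_quantile <- function(u, mean) {
  if (!is.numeric(u) || any(u < 0) || any(u >= 1))
    stop("u must lie in [0, 1)", call. = FALSE)
  if (!is.numeric(mean) || any(mean < 0))
    stop("mean must be non-negative", call. = FALSE)
  stats::qpois(u, mean)
}

#' Standard normal quantile
#'
#' `qnorm` restricted to the open unit interval, used to couple a uniform
#' stream coordinate to the Gaussian increment of the chemical Langevin
#' Euler-Maruyama step.
#'
#' @param u Uniform variate(s) strictly inside `(0, 1)`.
#' @return Numeric vector of standard normal quantiles.
#' @export
normal_quantile <- function(u) {
  if (!is.numeric(u) || any(u <= 0) || any(u >= 1))
    stop("u must lie strictly inside (0, 1)", call. = FALSE)
  stats::qnorm(u)
}

#' Simulation configuration
#'
#' Bundles the fixed-step simulation parameters. The grid takes
#' `ceiling(T / tau)` steps; when `T` is not a multiple of `tau` the final
#' step is truncated to `T - (steps - 1) * tau` so the trajectory ends at `T`
#' exactly.
#'
#' @param tau Step size, `> 0`.
#' @param T Final time, `>= tau`.
#' @param method `"tau_leap"` (discrete Poisson updates) or `"cle_em"`
#'   (Euler-Maruyama discretisation of the chemical Langevin equation).
#' @param negative_policy For tau-leaping: `"clamp"` resets negative
#'   post-update copy numbers to zero (needed for e.g. the Schlogl system);
#'   `"error"` aborts on a negative copy number. CLE states are allowed to go
#'   negative, the policy only guards the discrete simulator.
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(tau, T, method = c("tau_leap", "cle_em"),
                              negative_policy = c("clamp", "error")) {
  steps <- n_steps(T, tau)
  structure(list(tau = as.numeric(tau), T = as.numeric(T), steps = steps,
                 method = match.arg(method),
                 negative_policy = match.arg(negative_policy)),
            class = "simulation_config")
}

simulate_stream <- function(network, state, cfg, uniforms, cle) {
  stopifnot(inherits(network, "reaction_network"),
            inherits(cfg, "simulation_config"))
  x0 <- state_vector(state, network)
  K <- length(network$reactions)
  dim_needed <- cfg$steps * K
  if (length(uniforms) != dim_needed)
    stop("uniform stream has length ", length(uniforms), ", expected ",
         dim_needed, " (K * ceiling(T / tau))", call. = FALSE)
  if (any(uniforms < 0) || any(uniforms >= 1))
    stop("uniforms must lie in [0, 1)", call. = FALSE)
  frozen <- network$species %in% names(network$frozen)
  states <- .simulate_traj_cpp(as.numeric(uniforms), x0, network$alpha,
                               network$zeta, vapply(network$reactions,
                                                    `[[`, numeric(1), "rate"),
                               frozen, cfg$tau, cfg$T, cfg$steps, cle,
                               cfg$negative_policy == "clamp")
  if (!cle && cfg$negative_policy == "error" && any(states < 0))
    stop("negative copy number encountered under negative_policy = \"error\"",
         call. = FALSE)
  times <- c(seq_len(cfg$steps) - 1, 0) * cfg$tau
  times[cfg$steps + 1] <- cfg$T
  colnames(states) <- network$species
  structure(list(times = times, states = states, method = cfg$method),
            class = "trajectory")
}

#' Simulate one tau-leap sample path from a uniform stream
#'
#' Runs the fixed-step tau-leap scheme: at each step the propensities are
#' evaluated at the current state and each channel fires
#' `poisson_quantile(u_jk, a_k * tau)` times, where `u_jk` is the stream
#' coordinate for (step j, channel k). The path is a pure function of the
#' stream: identical streams give bit-identical trajectories.
#'
#' @param network A [reaction_network()].
#' @param state Initial [system_state()] (integer copy numbers).
#' @param cfg A [simulation_config()] with `method = "tau_leap"`.
#' @param uniforms Numeric vector of length `K * ceiling(T / tau)` in
#'   `[0, 1)`, typically a [stream_chunk()] of a point set.
#' @return An object of class `"trajectory"`: list with `times` (grid
#'   including 0 and `T`) and `states` (matrix, one row per grid time, one
#'   column per species).
#' @export
tau_leap_path <- function(network, state, cfg, uniforms) {
  simulate_stream(network, state, cfg, uniforms, cle = FALSE)
}

#' Simulate one chemical Langevin (Euler-Maruyama) path from a uniform stream
#'
#' Each step advances the real-valued state by
#' `sum_k (a_k * tau + sqrt(max(a_k, 0) * tau) * z_k) * zeta_k` with
#' `z_k = normal_quantile(u_jk)`. Propensities are evaluated on real states
#' with the falling factorials replaced by their polynomial extension; the
#' diffusion term clamps negative propensities to zero under the square
#' root. With all uniforms equal to 1/2 the step degenerates to the explicit
#' Euler step of the deterministic reaction rate equations.
#'
#' @inheritParams tau_leap_path
#' @return A `"trajectory"` with real-valued states.
#' @export
cle_em_path <- function(network, state, cfg, uniforms) {
  simulate_stream(network, state, cfg, uniforms, cle = TRUE)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory (%s): %d grid times, %d species, T = %g\n",
              x$method, length(x$times), ncol(x$states), max(x$times)))
  invisible(x)
}

#' Observable of the state at the final time
#'
#' @param species Species name or index whose copy number is read out.
#' @param power Exponent `k` for moment observables `g(x) = x^k` (default 1).
#' @return An object of class `"observable"`.
#' @export
observable <- function(species = 1L, power = 1) {
  stopifnot(length(species) == 1, is.numeric(power), length(power) == 1)
  structure(list(species = species, power = as.numeric(power)),
            class = "observable")
}

apply_observable <- function(g, states) {
  # states: matrix with one row per path (or per grid time), species columns
  stopifnot(inherits(g, "observable"))
  states[, g$species]^g$power
}

#' Evaluate an observable at the end of a trajectory
#'
#' @param traj A `"trajectory"` from [tau_leap_path()] or [cle_em_path()].
#' @param g An [observable()].
#' @return `g(X(T))`, a single number.
#' @export
final_value <- function(traj, g = observable()) {
  stopifnot(inherits(traj, "trajectory"))
  apply_observable(g, traj$states[nrow(traj$states), , drop = FALSE])
}

#' Simulate many paths at once and return their final states
#'
#' Drives one sample path per row of a point set and returns the states at
#' the final time only - the bulk workhorse behind [run_experiment()].
#'
#' @param network A [reaction_network()].
#' @param state Initial [system_state()].
#' @param cfg A [simulation_config()].
#' @param ps A `"point_set"` whose dimension is `K * ceiling(T / tau)`.
#' @return Numeric matrix, one row per path, one column per species.
#' @export
simulate_final_states <- function(network, state, cfg, ps) {
  stopifnot(inherits(network, "reaction_network"),
            inherits(cfg, "simulation_config"), inherits(ps, "point_set"))
  x0 <- state_vector(state, network)
  K <- length(network$reactions)
  if (ps$dimension != cfg$steps * K)
    stop("point set has dimension ", ps$dimension, ", expected ",
         cfg$steps * K, " (K * ceiling(T / tau))", call. = FALSE)
  finals <- .simulate_batch_cpp(ps$values, x0, network$alpha, network$zeta,
                                vapply(network$reactions, `[[`, numeric(1),
                                       "rate"),
                                network$species %in% names(network$frozen),
                                cfg$tau, cfg$T, cfg$steps,
                                cfg$method == "cle_em",
                                cfg$negative_policy == "clamp")
  colnames(finals) <- network$species
  finals
}

#' Write a trajectory to CSV
#'
#' One row per grid time, a `time` column followed by one column per
#' species; numbers are written with 17 significant digits so round trips
#' are exact.
#'
#' @param traj A `"trajectory"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  df <- data.frame(time = traj$times, traj$states, check.names = FALSE)
  write_csv17(df, path)
}

# CSV writer pinned to 17 significant digits for cross-platform determinism.
write_csv17 <- function(df, path) {
  fmt <- vapply(df, function(col) {
    if (is.numeric(col)) sprintf("%.17g", col) else as.character(col)
  }, character(nrow(df)))
  fmt <- matrix(fmt, nrow = nrow(df))
  lines <- c(paste(names(df), collapse = ","),
             apply(fmt, 1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}
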