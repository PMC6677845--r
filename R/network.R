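#' Define a single reaction channel
#'
#' A reaction channel is specified by its reactant and product stoichiometries
#' and a mass-action rate constant. Stoichiometries are given as named counts,
#' e.g. `c(S1 = 2, S2 = 1)` for a channel consuming two molecules of S1 and one
#' of S2; species not named have stoichiometry zero.
#'
#' @param reactants Named non-negative integer vector of reactant
#'   stoichiometries (may be empty for a pure source channel).
#' @param products Named non-negative integer vector of product
#'   stoichiometries (may be empty for a pure degradation channel).
#' @param rate Non-negative mass-action rate constant.
#' @return An object of class `"reaction"`.
#' @seealso [reaction_network()]
#' @export
#' @examples
#' reaction(c(S1 = 1), c(S1 = 2), rate = 1)  # autocatalytic birth
reaction <- function(reactants = numeric(), products = numeric(), rate) {
  check_stoich <- function(x, what) {
    x <- unlist(x)
    if (length(x) == 0) return(numeric())
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stop(what, " stoichiometries must be named by species", call. = FALSE)
    if (any(x < 0) || any(x != round(x)))
      stop(what, " stoichiometries must be non-negative integers", call. = FALSE)
    x
  }
  if (!is.numeric(rate) || length(rate) != 1 || is.na(rate) || rate < 0)
    stop("rate must be a single non-negative number", call. = FALSE)
  structure(list(reactants = check_stoich(reactants, "reactant"),
                 products = check_stoich(products, "product"),
                 rate = as.numeric(rate)),
            class = "reaction")
}

#' Define a well-mixed chemical reaction network
#'
#' Collects species and reaction channels into a network object used by the
#' simulators. Buffer species whose copy number is held constant (for example
#' the large reservoirs of the Schlogl system) are declared via `frozen`:
#' they enter propensities at their fixed value but are never updated.
#'
#' @param species Character vector of species names (length `n >= 1`).
#' @param reactions List of [reaction()] objects (length `K >= 1`), each
#'   referencing only species in `species`.
#' @param frozen Optional named numeric vector of fixed copy numbers for
#'   frozen species, e.g. `c(S2 = 1e5)`.
#' @return An object of class `"reaction_network"` with elements `species`,
#'   `reactions`, `frozen`, and derived stoichiometry matrices `alpha`
#'   (reactants, `n x K`), `beta` (products) and `zeta = beta - alpha`.
#' @export
#' @examples
#' reaction_network(
#'   species = "S1",
#'   reactions = list(reaction(c(S1 = 1), NULL, rate = 1),
#'                    reaction(c(S1 = 1), c(S1 = 2), rate = 1)))
reaction_network <- function(species, reactions, frozen = NULL) {
  if (!is.character(species) || length(species) < 1 || anyDuplicated(species))
    stop("species must be a character vector of distinct names", call. = FALSE)
  if (!is.list(reactions) || length(reactions) < 1 ||
      !all(vapply(reactions, inherits, logical(1), "reaction"))
  )
    stop("reactions must be a non-empty list of reaction() objects",
         call. = FALSE)
  n <- length(species)
  K <- length(reactions)
  alpha <- beta <- matrix(0L, n, K, dimnames = list(species, NULL))
  fill <- function(mat, stoich, k) {
    unknown <- setdiff(names(stoich), species)
    if (length(unknown) > 0)
      stop("reaction ", k, " references unknown species: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    mat[names(stoich), k] <- as.integer(stoich)
    mat
  }
  for (k in seq_len(K)) {
    alpha <- fill(alpha, reactions[[k]]$reactants, k)
    beta <- fill(beta, reactions[[k]]$products, k)
  }
  frozen <- unlist(frozen)
  if (length(frozen) > 0) {
    if (is.null(names(frozen)) || !all(names(frozen) %in% species))
      stop("frozen must be named by species in the network", call. = FALSE)
    if (any(frozen < 0)) stop("frozen copy numbers must be non-negative",
                              call. = FALSE)
  }
  structure(list(species = species, reactions = reactions,
                 frozen = frozen, alpha = alpha, beta = beta,
                 zeta = beta - alpha),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  n <- length(x$species)
  K <- length(x$reactions)
  cat("Reaction network:", n, "species,", K, "reaction channels\n")
  side <- function(stoich) {
    if (length(stoich) == 0) return("0")
    paste(ifelse(stoich > 1, paste0(stoich, " ", names(stoich)), names(stoich)),
          collapse = " + ")
  }
  for (k in seq_len(K)) {
    r <- x$reactions[[k]]
    cat(sprintf("  R%d: %s -> %s   (c = %g)\n", k, side(r$reactants),
                side(r$products), r$rate))
  }
  if (length(x$frozen) > 0)
    cat("  frozen:", paste(names(x$frozen), "=", format(x$frozen),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Create a system state
#'
#' @param copy_numbers Numeric vector of copy numbers, one per species of the
#'   network it will be used with (integer-valued for discrete simulation;
#'   the chemical Langevin path function accepts real values).
#' @param time Non-negative time stamp.
#' @return An object of class `"system_state"`.
#' @export
system_state <- function(copy_numbers, time = 0) {
  if (!is.numeric(copy_numbers) || length(copy_numbers) < 1)
    stop("copy_numbers must be a non-empty numeric vector", call. = FALSE)
  if (!is.numeric(time) || length(time) != 1 || time < 0)
    stop("time must be a single non-negative number", call. = FALSE)
  cn <- as.numeric(copy_numbers)
  names(cn) <- names(copy_numbers)
  structure(list(copy_numbers = cn, time = as.numeric(time)),
            class = "system_state")
}

# Coerce a state argument (system_state or bare vector) to a copy-number
# vector of the network's dimension, with frozen species forced to their
# fixed values.
state_vector <- function(state, network) {
  x <- if (inherits(state, "system_state")) state$copy_numbers else state
  if (!is.numeric(x) || length(x) != length(network$species))
    stop("state has ", length(x), " species, network has ",
         length(network$species), call. = FALSE)
  x <- as.numeric(x)
  names(x) <- network$species
  if (length(network$frozen) > 0)
    x[names(network$frozen)] <- network$frozen
  x
}

#' Mass-action propensities
#'
#' Evaluates the combinatorial mass-action propensity of every reaction
#' channel at a state: `a_k = c_k * prod_i choose(X_i, alpha_ik)`, the rate
#' constant times the number of distinct reactant combinations. A channel
#' with insufficient reactants (`X_i < alpha_ik` for some species) has
#' propensity zero. Frozen species contribute their fixed copy number.
#'
#' Note the combinatorial (copy-number) convention is used throughout, not
#' the concentration-style power law `x^alpha`; for bimolecular and higher
#' channels the two differ by falling-factorial corrections.
#'
#' @param state A [system_state()] or bare numeric vector of copy numbers.
#' @param network A [reaction_network()].
#' @return Non-negative numeric vector of length `K`.
#' @export
#' @examples
#' net <- builtin_model("birth_death", list(epsilon = 0.1, c = 1))
#' propensities(net$state, net$network)  # both channels linear in X
propensities <- function(state, network) {
  stopifnot(inherits(network, "reaction_network"))
  x <- state_vector(state, network)
  alpha <- network$alpha
  vapply(seq_along(network$reactions), function(k) {
    a <- network$reactions[[k]]$rate
    for (i in seq_along(x)) {
      al <- alpha[i, k]
      if (al == 0) next
      if (x[i] < al) return(0)
      a <- a * prod(x[i] - seq_len(al) + 1) / factorial(al)
    }
    a
  }, numeric(1))
}

#' Advance a state by given reaction firing counts
#'
#' Applies `X + sum_k p_k * zeta_k` for firing counts `p_k`, leaving frozen
#' species untouched. The result may contain negative entries; handling them
#' is the caller's (simulator's) responsibility.
#'
#' @param state A [system_state()] or numeric vector of copy numbers.
#' @param firing_counts Non-negative integer vector of length `K`.
#' @param network A [reaction_network()].
#' @return A [system_state()] with updated copy numbers (time unchanged).
#' @export
apply_reactions <- function(state, firing_counts, network) {
  stopifnot(inherits(network, "reaction_network"))
  x <- state_vector(state, network)
  K <- length(network$reactions)
  if (length(firing_counts) != K)
    stop("firing_counts must have length ", K, call. = FALSE)
  if (any(firing_counts < 0) || any(firing_counts != round(firing_counts)))
    stop("firing_counts must be non-negative integers", call. = FALSE)
  upd <- x + drop(network$zeta %*% as.numeric(firing_counts))
  if (length(network$frozen) > 0)
    upd[names(network$frozen)] <- network$frozen
  system_state(upd, time = if (inherits(state, "system_state")) state$time else 0)
}

#' Dimension of the fixed-step simulation problem
#'
#' A fixed-step simulation with `K` reaction channels run until time `T` with
#' step `tau` consumes exactly `K * ceiling(T / tau)` uniform variates per
#' sample path; this is the dimension of the point set that must be supplied.
#'
#' @param K Number of reaction channels (`>= 1`).
#' @param T Final time (`> 0`).
#' @param tau Step size (`0 < tau <= T`).
#' @return Integer dimension `K * ceiling(T / tau)`.
#' @export
#' @examples
#' problem_dimension(2, 1.6, 0.2)  # 16
#' problem_dimension(4, 4, 0.4)    # 40
problem_dimension <- function(K, T, tau) {
  if (!is.numeric(K) || length(K) != 1 || K < 1 || K != round(K))
    stop("K must be a positive integer", call. = FALSE)
  as.integer(K) * n_steps(T, tau)
}

# ceiling(T / tau) with a relative guard against floating-point ratios such
# as 1.6 / 0.2 landing a hair above an integer.
n_steps <- function(T, tau) {
  if (!is.numeric(T) || length(T) != 1 || T <= 0)
    stop("T must be a positive number", call. = FALSE)
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0 || tau > T + 1e-12)
    stop("tau must satisfy 0 < tau <= T", call. = FALSE)
  as.integer(ceiling(T / tau - 1e-9))
}

#' Built-in test systems
#'
#' Constructs one of three standard test networks together with its initial
#' state:
#' \describe{
#'   \item{`birth_death`}{Single-species linear birth-death process, channels
#'     `S1 -> 0` and `S1 -> 2 S1`, both with rate constant `c`. Parameters:
#'     `epsilon` (initial copy number is `1/epsilon`; default `1e-3`) and `c`
#'     (default 1). With equal rates the mean stays at `X(0)` and the variance
#'     grows as `2*c*t*X(0)`.}
#'   \item{`isomerisation`}{Closed two-species reversible isomerisation,
#'     `S1 -> S2` with rate `c` and `S2 -> S1` with rate `alpha * c`.
#'     Parameters: `c` (default 1), `alpha` (default `1e-4`), `epsilon`
#'     (default `1e-2`). The initial state `(1, 1/alpha) / epsilon` is the
#'     CTMC equilibrium, so the mean stays put; `X1 + X2` is conserved
#'     exactly along every path.}
#'   \item{`schlogl`}{Bistable Schlogl system: `2 S1 + S2 -> 3 S1` (c1),
#'     `3 S1 -> 2 S1 + S2` (c2), `S3 -> S1` (c3), `S1 -> S3` (c4), with the
#'     buffer species S2 and S3 frozen at large constant copy numbers.
#'     Defaults: `c1 = 3e-7`, `c2 = 1e-4`, `c3 = 1e-3`, `c4 = 3.5`,
#'     `S2 = 1e5`, `S3 = 2e5`, `X1_0 = 250`. Bistable around roughly 100 and
#'     550 molecules of S1.}
#' }
#'
#' @param name One of `"birth_death"`, `"isomerisation"`, `"schlogl"`.
#' @param params Named list overriding the defaults listed above.
#' @return A list with elements `network` ([reaction_network()]) and `state`
#'   ([system_state()] at time 0).
#' @export
#' @examples
#' bd <- builtin_model("birth_death", list(epsilon = 1e-3, c = 1))
#' bd$state$copy_numbers  # 1000
builtin_model <- function(name, params = list()) {
  if (!is.character(name) || length(name) != 1)
    stop("name must be a single model name", call. = FALSE)
  take <- function(key, default) {
    if (!is.null(params[[key]])) as.numeric(params[[key]]) else default
  }
  known <- list(
    birth_death = c("epsilon", "c"),
    isomerisation = c("epsilon", "c", "alpha"),
    schlogl = c("c1", "c2", "c3", "c4", "S2", "S3", "X1_0"))
  if (!name %in% names(known))
    stop("unknown model '", name, "'; available: ",
         paste(names(known), collapse = ", "), call. = FALSE)
  unknown <- setdiff(names(params), known[[name]])
  if (length(unknown) > 0)
    stop("unknown parameters for model '", name, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  switch(name,
    birth_death = {
      eps <- take("epsilon", 1e-3)
      cc <- take("c", 1)
      net <- reaction_network(
        species = "S1",
        reactions = list(reaction(c(S1 = 1), NULL, rate = cc),
                         reaction(c(S1 = 1), c(S1 = 2), rate = cc)))
      list(network = net, state = system_state(c(S1 = round(1 / eps))))
    },
    isomerisation = {
      eps <- take("epsilon", 1e-2)
      cc <- take("c", 1)
      al <- take("alpha", 1e-4)
      net <- reaction_network(
        species = c("S1", "S2"),
        reactions = list(reaction(c(S1 = 1), c(S2 = 1), rate = cc),
                         reaction(c(S2 = 1), c(S1 = 1), rate = al * cc)))
      list(network = net,
           state = system_state(round(c(S1 = 1, S2 = 1 / al) / eps)))
    },
    schlogl = {
      s2 <- take("S2", 1e5)
      s3 <- take("S3", 2e5)
      net <- reaction_network(
        species = c("S1", "S2", "S3"),
        reactions = list(
          reaction(c(S1 = 2, S2 = 1), c(S1 = 3), rate = take("c1", 3e-7)),
          reaction(c(S1 = 3), c(S1 = 2, S2 = 1), rate = take("c2", 1e-4)),
          reaction(c(S3 = 1), c(S1 = 1), rate = take("c3", 1e-3)),
          reaction(c(S1 = 1), c(S3 = 1), rate = take("c4", 3.5))),
        frozen = c(S2 = s2, S3 = s3))
      list(network = net,
           state = system_state(c(S1 = take("X1_0", 250), S2 = s2, S3 = s3)))
    })
}
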