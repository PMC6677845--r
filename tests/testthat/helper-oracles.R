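# Independent oracles used across the test files. These deliberately avoid
# the code paths they check: combination counts are enumerated, Poisson
# CDFs are summed term by term, and quadrature moments come from explicit
# grids.

# Mass-action propensity by explicit enumeration: count the distinct
# reactant combinations by listing them (combn), never via choose().
oracle_propensity <- function(x, alpha, rate) {
  combos <- 1
  for (i in seq_along(x)) {
    a <- alpha[i]
    if (a == 0) next
    if (x[i] < a) return(0)
    combos <- combos * ncol(utils::combn(x[i], a))
  }
  rate * combos
}

# Smallest q with sum_{j<=q} e^-lambda lambda^j / j! >= u, by direct
# term-by-term summation (recursive pmf, no stats:: quantile functions).
oracle_poisson_quantile <- function(u, lambda) {
  if (lambda == 0) return(0)
  term <- exp(-lambda)
  acc <- term
  q <- 0
  while (acc < u) {
    q <- q + 1
    term <- term * lambda / q
    acc <- acc + term
    if (q > 1e7) stop("oracle runaway")
  }
  q
}

# One tau-leap path stepped in plain R with qpois, used to cross-check the
# compiled batch simulator (shared inverse-transform convention, separate
# implementation of the loop, propensities via the exported R function).
oracle_tau_leap <- function(network, x0, tau, T, uniforms) {
  steps <- ceiling(T / tau - 1e-9)
  K <- length(network$reactions)
  x <- x0
  for (j in seq_len(steps)) {
    tau_j <- if (j == steps) T - (steps - 1) * tau else tau
    a <- propensities(x, network)
    p <- stats::qpois(uniforms[(j - 1) * K + seq_len(K)], a * tau_j)
    x <- x + drop(network$zeta %*% p)
    if (length(network$frozen) > 0)
      x[match(names(network$frozen), network$species)] <- network$frozen
  }
  x
}
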