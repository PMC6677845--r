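#' Pseudo-random uniform point set
#'
#' An `N x s` matrix of i.i.d. uniform variates on `[0,1)`, the Monte Carlo
#' baseline input stream. One row drives one sample path.
#'
#' @param n Number of points (rows), `>= 1`.
#' @param s Dimension (columns), `>= 1`.
#' @param seed Integer seed; identical seeds give identical matrices.
#' @return An object of class `"point_set"`: a list with `values` (`n x s`
#'   matrix), `generator_kind`, `dimension`, `count` and `seed`.
#' @export
pseudo_points <- function(n, s, seed) {
  check_point_args(n, s)
  set.seed(seed)
  new_point_set(matrix(stats::runif(n * s), nrow = n, ncol = s),
                "pseudo", seed)
}

#' Randomised Sobol' low-discrepancy point set
#'
#' The first `n` points of an `s`-dimensional Sobol' sequence (a base-2
#' digital net, Joe-Kuo direction numbers), randomised by a linear matrix
#' scramble followed by a digital shift in the sense of Matousek. The
#' randomisation preserves the digital-net equidistribution structure while
#' making every point marginally uniform on `[0,1)^s`, which is what makes
#' the randomised QMC estimator unbiased and its empirical variance
#' meaningful.
#'
#' The full dimension `s` must be requested up front: low-discrepancy point
#' sets cannot be assembled by concatenating independent lower-dimensional
#' sets, unlike pseudo-random ones.
#'
#' @param n Number of points; powers of two preserve the balance properties
#'   of the net, other counts are allowed with a warning.
#' @param s Dimension, `1 <= s <= 160` (the embedded direction-number table).
#' @param seed Integer seed for the randomisation; distinct seeds give
#'   independent randomisations of the same underlying net.
#' @param scramble,shift Logical; disable to expose the deterministic base
#'   sequence (whose first point is the origin). Both `TRUE` for RQMC use.
#' @return A `"point_set"` (see [pseudo_points()]) with
#'   `generator_kind = "sobol_randomised"` (or `"sobol"` when both
#'   randomisations are disabled).
#' @export
#' @examples
#' ps <- sobol_points(2^6, 2, seed = 1)
#' colMeans(ps$values)  # close to 1/2
sobol_points <- function(n, s, seed, scramble = TRUE, shift = TRUE) {
  check_point_args(n, s)
  if (s > .sobol_max_dim)
    stop("dimension s = ", s, " exceeds the available direction numbers (",
         .sobol_max_dim, ")", call. = FALSE)
  if (bitwAnd(n, n - 1L) != 0L)
    warning("n = ", n, " is not a power of two; the Sobol' net loses its ",
            "balance properties at such counts", call. = FALSE)
  set.seed(seed)
  vals <- .sobol_points_cpp(n, s, .sobol_poly, .sobol_vinit, scramble, shift)
  new_point_set(vals, if (scramble || shift) "sobol_randomised" else "sobol",
                seed)
}

check_point_args <- function(n, s) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n))
    stop("n must be a positive integer", call. = FALSE)
  if (!is.numeric(s) || length(s) != 1 || s < 1 || s != round(s))
    stop("s must be a positive integer", call. = FALSE)
}

new_point_set <- function(values, kind, seed) {
  structure(list(values = values, generator_kind = kind,
                 dimension = ncol(values), count = nrow(values),
                 seed = seed),
            class = "point_set")
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("Point set: %d x %d (%s, seed %s)\n", x$count, x$dimension,
              x$generator_kind, format(x$seed)))
  invisible(x)
}

#' Extract the uniform stream for one sample path
#'
#' Returns row `path_index` of the point set: the stream of uniforms that
#' drives one sample path. Within the row, the variate for time step `j` and
#' reaction channel `k` sits at flat position `(j - 1) * K + k` (see
#' [stream_index()]); the earliest, best-distributed Sobol' coordinates thus
#' drive the earliest time steps.
#'
#' @param ps A `"point_set"`.
#' @param path_index Row index in `1..count`.
#' @return Numeric vector of length `dimension`.
#' @export
stream_chunk <- function(ps, path_index) {
  stopifnot(inherits(ps, "point_set"))
  if (!is.numeric(path_index) || length(path_index) != 1 ||
      path_index < 1 || path_index > ps$count || path_index != round(path_index))
    stop("path_index must be in 1..", ps$count, call. = FALSE)
  ps$values[path_index, ]
}

#' Flat stream coordinate of a (time step, reaction) pair
#'
#' @param step Time step index, 1-based.
#' @param reaction Reaction channel index, 1-based, in `1..K`.
#' @param K Number of reaction channels.
#' @return The 1-based column index `(step - 1) * K + reaction`.
#' @export
#' @examples
#' stream_index(3, 2, K = 2)  # 6th coordinate
stream_index <- function(step, reaction, K) {
  stopifnot(step >= 1, reaction >= 1, reaction <= K)
  as.integer((step - 1) * K + reaction)
}
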