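#' Construct a random sparse reservoir adjacency matrix
#'
#' Draws an N x N matrix whose entries are independently nonzero with
#' probability `connection_prob`, with nonzero values uniform on \[-1, 1\],
#' then rescales it so that the magnitude of its largest eigenvalue (the
#' spectral radius) equals `spectral_radius`. Diagonal entries are treated
#' like any other entry.
#'
#' `spectral_radius = 0` is permitted and returns the zero matrix (the limit
#' of the rescaling), so that parameter sweeps can include the degenerate
#' endpoint. If the *base* draw itself has spectral radius 0 (e.g. a
#' nilpotent draw, possible at very small N), the rescaling is undefined and
#' an error is raised; redraw with a different seed.
#'
#' @param n_nodes number of reservoir nodes N (>= 1).
#' @param connection_prob per-element probability P of a nonzero entry,
#'   in (0, 1].
#' @param spectral_radius target spectral radius rho (>= 0).
#' @param seed integer seed; the same seed reproduces the matrix
#'   bit-identically.
#' @return an N x N numeric matrix.
#' @seealso [reservoir_realization()], [measure_spectral_radius()]
#' @export
make_adjacency <- function(n_nodes, connection_prob, spectral_radius, seed) {
  stopifnot(n_nodes >= 1, connection_prob > 0, connection_prob <= 1,
            spectral_radius >= 0)
  base <- withr::with_seed(seed, {
    mask <- stats::runif(n_nodes * n_nodes) < connection_prob
    vals <- stats::runif(n_nodes * n_nodes, -1, 1)
    matrix(ifelse(mask, vals, 0), n_nodes, n_nodes)
  })
  rescale_to_radius(base, spectral_radius)
}

#' @keywords internal
rescale_to_radius <- function(base, spectral_radius,
                              base_sr = measure_spectral_radius(base)) {
  if (spectral_radius == 0) return(base * 0)  # limit of the rescaling
  if (base_sr == 0) {
    stop("rescaling undefined: base matrix has spectral radius 0 ",
         "(e.g. nilpotent draw); redraw with a new seed")
  }
  base * (spectral_radius / base_sr)
}

#' Construct the random input matrix
#'
#' Each of the N rows has exactly one nonzero entry: the column is chosen
#' uniformly at random among the D input components and the value uniformly
#' on \[-1, 1\]. Each reservoir node is therefore driven by a single
#' component of the input signal.
#'
#' @param n_nodes number of rows N (>= 1).
#' @param input_dim number of input components D (>= 1); 2 for the
#'   seeing-double task.
#' @param seed integer seed (bit-identical reproduction).
#' @return an N x D numeric matrix with one nonzero per row.
#' @export
make_input_weights <- function(n_nodes, input_dim, seed) {
  stopifnot(n_nodes >= 1, input_dim >= 1)
  withr::with_seed(seed, {
    cols <- sample.int(input_dim, n_nodes, replace = TRUE)
    vals <- stats::runif(n_nodes, -1, 1)
    W <- matrix(0, n_nodes, input_dim)
    W[cbind(seq_len(n_nodes), cols)] <- vals
    W
  })
}

#' Spectral radius of a square matrix
#'
#' The maximum modulus over all eigenvalues.
#'
#' @param m a square numeric matrix.
#' @return a non-negative real number.
#' @export
measure_spectral_radius <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("matrix must be square")
  max(Mod(eigen(m, only.values = TRUE)$values))
}

#' A fixed random reservoir realization
#'
#' Bundles the sparse adjacency matrix M, the input matrix W_in, and the
#' generation parameters into one object. The *base* (pre-rescaling)
#' adjacency is stored alongside the rescaled one, so that a continuation
#' sweep can vary the spectral radius by pure rescaling of one fixed random
#' draw via [with_spectral_radius()] — the random structure never changes
#' along a sweep, only rho does.
#'
#' The input matrix is drawn with derived seed `seed + 1`, so one `seed`
#' fixes the whole realization.
#'
#' @param spectral_radius target spectral radius rho (>= 0).
#' @param seed integer seed (< 2^31 - 2); fixes both matrices.
#' @param n_nodes reservoir size N; the value 100 keeps desk-scale sweeps
#'   cheap while remaining an order of magnitude above the input dimension.
#' @param input_dim input dimension D (2 for planar orbits).
#' @param connection_prob per-element connection probability P.
#' @return an object of class `reservoir_realization` with elements
#'   `adjacency`, `base_adjacency`, `input_weights`, `base_spectral_radius`
#'   and the generation parameters.
#' @export
reservoir_realization <- function(spectral_radius, seed, n_nodes = 100,
                                  input_dim = 2, connection_prob = 0.04) {
  stopifnot(is.numeric(seed), length(seed) == 1, abs(seed) < 2^31 - 2)
  seed <- as.integer(seed)
  base <- withr::with_seed(seed, {
    mask <- stats::runif(n_nodes * n_nodes) < connection_prob
    vals <- stats::runif(n_nodes * n_nodes, -1, 1)
    matrix(ifelse(mask, vals, 0), n_nodes, n_nodes)
  })
  x <- structure(list(
    adjacency = rescale_to_radius(base, spectral_radius),
    base_adjacency = base,
    base_spectral_radius = measure_spectral_radius(base),
    input_weights = make_input_weights(n_nodes, input_dim, seed + 1L),
    n_nodes = as.integer(n_nodes),
    input_dim = as.integer(input_dim),
    connection_prob = connection_prob,
    spectral_radius = spectral_radius,
    seed = seed
  ), class = "reservoir_realization")
  validate_realization(x)
  x
}

#' Rescale a realization to a new spectral radius
#'
#' Returns a copy of `realization` whose adjacency is the *same* base random
#' draw rescaled to `rho`. Matrices obtained for two different radii from
#' one realization are exactly elementwise proportional.
#'
#' @param realization a [reservoir_realization()].
#' @param rho new target spectral radius (>= 0).
#' @return a `reservoir_realization`.
#' @export
with_spectral_radius <- function(realization, rho) {
  stopifnot(inherits(realization, "reservoir_realization"), rho >= 0)
  realization$adjacency <- rescale_to_radius(
    realization$base_adjacency, rho, realization$base_spectral_radius)
  realization$spectral_radius <- rho
  realization
}

#' Validate the invariants of a reservoir realization
#'
#' Checks: the rescaled adjacency has spectral radius equal to the stored
#' rho (within 1e-8); every input-weight row has exactly one nonzero entry
#' in \[-1, 1\]; all nonzero base-adjacency entries lie in \[-1, 1\].
#' Raises an error on violation, otherwise returns the object invisibly.
#'
#' @param x a `reservoir_realization`.
#' @export
validate_realization <- function(x) {
  stopifnot(inherits(x, "reservoir_realization"))
  sr <- measure_spectral_radius(x$adjacency)
  if (abs(sr - x$spectral_radius) > 1e-8)
    stop(sprintf("adjacency spectral radius %.12g != stored rho %.12g", sr,
                 x$spectral_radius))
  nz_per_row <- rowSums(x$input_weights != 0)
  if (!all(nz_per_row == 1))
    stop("input_weights must have exactly one nonzero per row")
  nzv <- x$input_weights[x$input_weights != 0]
  if (any(abs(nzv) > 1)) stop("input weight values must lie in [-1, 1]")
  bnz <- x$base_adjacency[x$base_adjacency != 0]
  if (any(abs(bnz) > 1)) stop("base adjacency nonzeros must lie in [-1, 1]")
  invisible(x)
}

#' @export
print.reservoir_realization <- function(x, ...) {
  cat(sprintf(
    "<reservoir_realization> N = %d, D = %d, P = %g, rho = %g, seed = %d\n",
    x$n_nodes, x$input_dim, x$connection_prob, x$spectral_radius, x$seed))
  cat(sprintf("  adjacency nonzeros: %d (%.3f%% dense)\n",
              sum(x$adjacency != 0),
              100 * mean(x$adjacency != 0)))
  invisible(x)
}
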