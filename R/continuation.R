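#' Local maxima of a scalar series
#'
#' Three-point stencil: values v_k with v_{k-1} < v_k >= v_{k+1}. The first
#' point of a plateau counts once; endpoints never count. The leading
#' `discard_fraction` of the series is dropped first (transient removal).
#'
#' @param series numeric vector.
#' @param discard_fraction leading fraction to discard (default 0).
#' @return numeric vector of local-maximum values (possibly empty).
#' @export
local_maxima <- function(series, discard_fraction = 0) {
  stopifnot(discard_fraction >= 0, discard_fraction < 1)
  keep <- seq.int(floor(length(series) * discard_fraction) + 1,
                  length(series))
  v <- series[keep]
  if (length(v) < 3) stop("series too short after discard (need >= 3 points)")
  k <- 2:(length(v) - 1)
  v[k][v[k - 1] < v[k] & v[k] >= v[k + 1]]
}

#' Classify the attractor behind a projected trajectory
#'
#' Labels a closed-loop projected trajectory as one of `fixed_point`
#' (late-time displacement below `1e-3 * b` over the last quarter of the
#' window), `orbit_A` / `orbit_B` (no relay transitions and the mean
#' x-coordinate on the matching side), `switching` (at least two relay
#' transitions in each direction), or `other`.
#'
#' @param projected T x 2 matrix (or `closed_loop_trajectory`) covering
#'   several orbit periods after the transient.
#' @param times matching times (defaults to row index * tau not needed for
#'   classification; only relative spacing matters).
#' @param pair the [task_pair()].
#' @param thresholds a [relay_thresholds()].
#' @param discard_fraction leading fraction treated as transient.
#' @return a single string label.
#' @export
classify_attractor <- function(projected, times = NULL, pair,
                               thresholds = relay_thresholds(),
                               discard_fraction = 0.5) {
  if (inherits(projected, "closed_loop_trajectory")) {
    times <- projected$times
    projected <- projected$projected
  }
  n <- nrow(projected)
  if (is.null(times)) times <- seq_len(n)
  keep <- seq.int(floor(n * discard_fraction) + 1, n)
  pts <- projected[keep, , drop = FALSE]
  # fixed point: last-quarter displacement from the final point
  lq <- seq.int(floor(n * 0.75) + 1, n)
  fin <- projected[n, ]
  disp <- sqrt((projected[lq, 1] - fin[1])^2 + (projected[lq, 2] - fin[2])^2)
  if (max(disp) < 1e-3 * pair$b) return("fixed_point")
  tr <- relay_transitions(pts[, 1], times[keep], thresholds,
                          high_state = "A")
  n_to_A <- sum(tr$entries$entered_state == "A")
  n_to_B <- sum(tr$entries$entered_state == "B")
  if (n_to_A >= 2 && n_to_B >= 2) return("switching")
  if (nrow(tr$entries) == 0) {
    mx <- mean(pts[, 1])
    if (mx > 0) return("orbit_A")
    if (mx < 0) return("orbit_B")
  }
  "other"
}

#' Attractor continuation in the spectral radius
#'
#' The tracking protocol: starting from `rho_start` (where the trained
#' closed loop is expected to be multifunctional), decrease rho in steps of
#' `rho_step` down to `rho_end`. At every rho the *same* base random
#' matrices are rescaled and the readout is retrained with the identical
#' input sequences, so rho is the only quantity varying along the sweep.
#' Two branches are tracked — one per orbit. At the first rho each branch
#' starts from its orbit's end-of-training state; afterwards each branch is
#' re-initialized from its own final state at the previous rho, the
#' simplest point on (or near) the attractor being followed. Each branch is
#' integrated for `t_track`, the first `discard_fraction` is dropped, and
#' the local maxima of the projected x-variable (`x_m`) are recorded
#' together with an attractor label. When a branch's reconstruction is
#' lost, the carried state simply follows whatever attractor the closed
#' loop approaches next, so the branch continues as a record of the
#' successor attractor.
#'
#' @param realization a [reservoir_realization()] (any stored rho).
#' @param params an [rc_params()].
#' @param pair a [task_pair()].
#' @param rho_start,rho_end sweep limits, `rho_start > rho_end > 0`.
#' @param rho_step decrement (> 0; 0.001 for fine sweeps, 0.01 for
#'   desk-scale ones).
#' @param config a [train_config()].
#' @param t_track integration time per rho per branch (default 200).
#' @param thresholds relay thresholds used by the classifier.
#' @param discard_fraction leading fraction of each tracking window
#'   discarded before collecting x_m (default 0.5).
#' @return an object of class `continuation_table`: a data.frame with one
#'   row per (rho, branch): `rho`, `branch_id`, `label`, `n_xm`, and a
#'   list-column `xm`; carried states are in `attr(, "carried_states")`.
#' @export
continuation_sweep <- function(realization, params, pair, rho_start,
                               rho_end, rho_step, config, t_track = 200,
                               thresholds = relay_thresholds(),
                               discard_fraction = 0.5) {
  stopifnot(rho_start >= rho_end, rho_end > 0, rho_step > 0)
  if (rho_start > rho_end && rho_step > rho_start - rho_end + 1e-9)
    stop("rho_step larger than the sweep range")
  rhos <- seq(rho_start, rho_end, by = -rho_step)
  n_steps <- round(t_track / params$tau)
  branch_states <- NULL
  rows <- vector("list", 2 * length(rhos))
  for (i in seq_along(rhos)) {
    rho <- rhos[i]
    trained <- train_seeing_double(with_spectral_radius(realization, rho),
                                   params, pair, config)
    if (is.null(branch_states))
      branch_states <- list(branch_A = trained$end_state_A,
                            branch_B = trained$end_state_B)
    for (b in names(branch_states)) {
      run <- integrate_closed_loop(trained, branch_states[[b]], n_steps)
      xm <- local_maxima(run$projected[, 1], discard_fraction)
      label <- classify_attractor(run$projected, run$times, pair,
                                  thresholds, discard_fraction)
      branch_states[[b]] <- run$final_state
      rows[[2 * (i - 1) + match(b, names(branch_states))]] <-
        list(rho = rho, branch_id = b, label = label, xm = xm)
    }
  }
  out <- data.frame(
    rho = vapply(rows, `[[`, numeric(1), "rho"),
    branch_id = vapply(rows, `[[`, character(1), "branch_id"),
    label = vapply(rows, `[[`, character(1), "label"),
    n_xm = vapply(rows, function(r) length(r$xm), integer(1)))
  out$xm <- lapply(rows, `[[`, "xm")
  attr(out, "carried_states") <- branch_states
  class(out) <- c("continuation_table", class(out))
  out
}

#' Flatten a continuation table to one row per local maximum
#'
#' The long format behind bifurcation-diagram panels: columns `rho`,
#' `branch_id`, `xm`, `label`.
#'
#' @param table a `continuation_table`.
#' @return a plain data.frame.
#' @export
continuation_long <- function(table) {
  n <- vapply(table$xm, length, integer(1))
  data.frame(rho = rep(table$rho, n),
             branch_id = rep(table$branch_id, n),
             xm = unlist(table$xm, use.names = FALSE),
             label = rep(table$label, n))
}

#' Probe for coexisting attractors from random initial conditions
#'
#' Draws `k` uniform states in \[-1, 1\]^N, integrates the closed loop from
#' each, and returns the classification of each endpoint trajectory —
#' a check that no untrained attractor is overlooked at a given rho.
#'
#' @param trained a `trained_rc`.
#' @param pair the [task_pair()].
#' @param k number of random probes.
#' @param t_probe integration time per probe.
#' @param seed RNG seed for the probe draws.
#' @param thresholds relay thresholds for classification.
#' @return a data.frame with `probe`, `label`.
#' @export
probe_basins <- function(trained, pair = trained$pair, k = 10,
                         t_probe = 200, seed = 1,
                         thresholds = relay_thresholds()) {
  N <- trained$realization$n_nodes
  n_steps <- round(t_probe / trained$params$tau)
  starts <- withr::with_seed(seed,
    matrix(stats::runif(k * N, -1, 1), k, N))
  labels <- vapply(seq_len(k), function(i) {
    run <- integrate_closed_loop(trained, starts[i, ], n_steps)
    classify_attractor(run$projected, run$times, pair, thresholds)
  }, character(1))
  data.frame(probe = seq_len(k), label = labels)
}
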