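#' Reservoir dynamics parameters
#'
#' Parameters of the leaky tanh reservoir ODE
#' `dr/dt = gamma * (-r + tanh(M r + sigma W_in u))`.
#'
#' Defaults: `gamma = 10` makes the reservoir timescale about ten times
#' faster than the 2*pi orbit period of the driving signals; `sigma = 0.1`
#' keeps `sigma * W_in * u` inside the responsive range of tanh for inputs
#' up to |u| ~ 13.5; `tau = 0.01` is the fixed Runge-Kutta step. The
#' stability guard `tau * gamma < 1` is enforced.
#'
#' @param gamma decay rate (1/time), > 0.
#' @param sigma input strength, >= 0.
#' @param tau integration step (time), > 0.
#' @return an object of class `rc_params`.
#' @export
rc_params <- function(gamma = 10, sigma = 0.1, tau = 0.01) {
  stopifnot(gamma > 0, sigma >= 0, tau > 0)
  if (tau * gamma >= 1)
    stop("tau * gamma must be < 1 for stable explicit stepping")
  structure(list(gamma = gamma, sigma = sigma, tau = tau),
            class = "rc_params")
}

#' Right-hand side of the driven (open-loop) reservoir ODE
#'
#' @param state reservoir state vector r (length N).
#' @param input_value input vector u (length D).
#' @param realization a [reservoir_realization()].
#' @param params an [rc_params()].
#' @return the derivative vector, length N.
#' @export
open_loop_derivative <- function(state, input_value, realization, params) {
  if (length(state) != realization$n_nodes)
    stop("state length does not match n_nodes")
  if (length(input_value) != realization$input_dim)
    stop("input length does not match input_dim")
  params$gamma * (-state + tanh(
    drop(realization$adjacency %*% state) +
      params$sigma * drop(realization$input_weights %*% input_value)))
}

as_sparse <- function(m) methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")

#' Integrate the driven reservoir with fixed-step RK4
#'
#' Integrates `dr/dt = gamma * (-r + tanh(M r + sigma W_in u(t)))` for
#' `n_steps` steps of size `tau`. The input must be available at every RK4
#' substep (half-step resolution): pass either a function of time, which is
#' evaluated exactly at `t + tau/2` for the middle stages, or a precomputed
#' D x (2*n_steps + 1) matrix sampled on the half-step grid.
#'
#' @param realization a [reservoir_realization()].
#' @param params an [rc_params()].
#' @param input a function `f(t)` returning a length(t) x D matrix (or a
#'   D-vector for scalar t), or a D x (2*n_steps + 1) numeric matrix.
#' @param n_steps number of steps; the trajectory has `n_steps + 1` states.
#' @param r0 initial state; defaults to the zero vector.
#' @param t0 initial time (default 0).
#' @return a `state_trajectory`: list with `times` (length n_steps + 1) and
#'   `states` ((n_steps + 1) x N matrix).
#' @export
integrate_open_loop <- function(realization, params, input, n_steps,
                                r0 = NULL, t0 = 0) {
  stopifnot(inherits(realization, "reservoir_realization"),
            inherits(params, "rc_params"), n_steps >= 0)
  N <- realization$n_nodes
  if (is.null(r0)) r0 <- numeric(N)
  stopifnot(length(r0) == N)
  times <- t0 + (0:n_steps) * params$tau
  if (n_steps == 0) {
    return(structure(list(times = times, states = matrix(r0, 1, N)),
                     class = "state_trajectory"))
  }
  half_times <- t0 + (0:(2 * n_steps)) * (params$tau / 2)
  if (is.function(input)) {
    u <- input(half_times)
    u_half <- if (is.matrix(u)) t(u) else matrix(u, nrow = realization$input_dim)
  } else {
    u_half <- as.matrix(input)
  }
  if (nrow(u_half) != realization$input_dim ||
      ncol(u_half) < 2 * n_steps + 1)
    stop("input series too short or wrong dimension: need D x (2*n_steps+1)")
  states <- rk4_open_cpp(as_sparse(realization$adjacency),
                         realization$input_weights,
                         params$gamma, params$sigma, params$tau,
                         r0, u_half, as.integer(n_steps))
  structure(list(times = times, states = states), class = "state_trajectory")
}

#' Integrate the autonomous (closed-loop) reservoir
#'
#' Integrates `dr/dt = gamma * (-r + tanh(M r + sigma W_in W_out q(r)))`,
#' where the trained readout replaces the external drive. The projected
#' prediction `u_hat(t) = W_out q(r(t))` is recorded at every step; full
#' reservoir states are recorded only on request.
#'
#' The tanh saturation makes the box \[-1, 1\]^N globally attracting, so the
#' closed loop can never diverge; a guard aborts (naming the step) if any
#' component exceeds 10, which only an implementation defect could produce.
#'
#' @param trained a [train_seeing_double()] result (`trained_rc`), or any
#'   list with elements `realization`, `params`, `readout`, `features`.
#' @param r0 initial state (length N), e.g. one of the trained end states.
#' @param n_steps number of RK4 steps.
#' @param record_states record the full N-dimensional states as well.
#' @param t0 initial time for the `times` axis.
#' @return a `closed_loop_trajectory`: list with `times`, `projected`
#'   ((n_steps + 1) x D), `final_state`, and optionally `states`.
#' @export
integrate_closed_loop <- function(trained, r0, n_steps,
                                  record_states = FALSE, t0 = 0) {
  realization <- trained$realization
  params <- trained$params
  stopifnot(length(r0) == realization$n_nodes, n_steps >= 0)
  quadratic <- identical(trained$features, "quadratic")
  expected <- if (quadratic) 2L * realization$n_nodes else realization$n_nodes
  if (ncol(trained$readout) != expected)
    stop("readout has ", ncol(trained$readout), " columns, expected ", expected)
  res <- rk4_closed_cpp(as_sparse(realization$adjacency),
                        realization$input_weights, trained$readout,
                        params$gamma, params$sigma, params$tau,
                        r0, as.integer(n_steps), quadratic, record_states,
                        diverge_guard = 10)
  out <- list(times = t0 + (0:n_steps) * params$tau,
              projected = res$projected,
              final_state = drop(res$final_state))
  if (record_states) out$states <- res$states
  structure(out, class = "closed_loop_trajectory")
}

#' Project reservoir states to the prediction space
#'
#' `u_hat = W_out q(r)` with `q` the feature map used in training.
#'
#' @param readout D x 2N (quadratic features) or D x N (linear) matrix.
#' @param state a length-N state vector or a T x N matrix of states.
#' @param features `"quadratic"` (default) or `"linear"`.
#' @return a length-D vector, or a T x D matrix for matrix input.
#' @export
project <- function(readout, state, features = "quadratic") {
  single <- !is.matrix(state)
  s <- if (single) matrix(state, 1) else state
  q <- if (identical(features, "quadratic")) cbind(s, s^2) else s
  if (ncol(q) != ncol(readout)) stop("state/readout shapes inconsistent")
  out <- q %*% t(readout)
  if (single) drop(out) else out
}

#' @export
print.state_trajectory <- function(x, ...) {
  cat(sprintf("<state_trajectory> %d states of dim %d, t in [%g, %g]\n",
              nrow(x$states), ncol(x$states), x$times[1],
              x$times[length(x$times)]))
  invisible(x)
}

#' @export
print.closed_loop_trajectory <- function(x, ...) {
  cat(sprintf("<closed_loop_trajectory> %d steps, t in [%g, %g]%s\n",
              length(x$times) - 1, x$times[1], x$times[length(x$times)],
              if (is.null(x$states)) " (projection only)" else ""))
  invisible(x)
}
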