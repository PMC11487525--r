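#' Quadratic state features
#'
#' The feature map `q(r) = [r; r^2]` (elementwise square). Appending the
#' squares breaks the odd symmetry of the tanh flow, which suppresses the
#' spurious "mirror attractors" (sign-flipped copies of the reconstructed
#' orbits) that a purely linear readout admits.
#'
#' @param state a length-N vector or a T x N matrix of states.
#' @return a length-2N vector, or a T x 2N matrix for matrix input.
#' @export
quad_features <- function(state) {
  if (is.matrix(state)) cbind(state, state^2) else c(state, state^2)
}

#' Training-stage configuration
#'
#' The open loop is driven from the zero initial state; states before
#' `t_listen` (the listening stage / washout) are discarded so the harvested
#' states depend only on the input history, not the initial condition.
#' States from `t_listen` to `t_train` populate the regression matrices.
#'
#' Defaults `t_listen = 50`, `t_train = 550` give roughly 80 orbit periods
#' of training data (50,000 columns at tau = 0.01, far more than the 2N
#' feature dimension); `ridge_param = 1e-4` is a small ridge that keeps the
#' normal equations well conditioned without visibly biasing the fit.
#'
#' @param t_listen washout duration (>= 0).
#' @param t_train end of the training window (> t_listen).
#' @param ridge_param ridge penalty (>= 0) on the readout regression.
#' @param tau sampling/integration step; must match the dynamics step.
#' @return an object of class `train_config`.
#' @export
train_config <- function(t_listen = 50, t_train = 550, ridge_param = 1e-4,
                         tau = 0.01) {
  stopifnot(t_listen >= 0, t_train > t_listen, ridge_param >= 0, tau > 0)
  structure(list(t_listen = t_listen, t_train = t_train,
                 ridge_param = ridge_param, tau = tau),
            class = "train_config")
}

#' Harvest driven reservoir states for readout training
#'
#' Drives the open loop with `input` from the zero state over
#' `[0, t_train]` and returns the feature matrix `[q(r(t_listen)), ...,
#' q(r(t_train))]` (2N x T), the matching targets `u(t)` (D x T), and the
#' end-of-training state `r(t_train)`.
#'
#' @param realization a [reservoir_realization()].
#' @param params an [rc_params()]; `params$tau` must equal `config$tau`.
#' @param input an input function `f(t)` (e.g. [orbit_input()]) or a
#'   half-step-sampled matrix, as for [integrate_open_loop()].
#' @param config a [train_config()].
#' @return a list with `features` (2N x T), `targets` (D x T),
#'   `end_state` (length N), and `times` (the T harvested times).
#' @export
harvest <- function(realization, params, input, config) {
  stopifnot(inherits(config, "train_config"))
  if (abs(params$tau - config$tau) > 1e-12)
    stop("train_config tau must equal dynamics tau")
  n_train <- round(config$t_train / config$tau)
  n_listen <- round(config$t_listen / config$tau)
  n_cols <- n_train - n_listen + 1
  if (n_cols < 2 * realization$n_nodes)
    stop("training window too short: ", n_cols, " columns < 2N = ",
         2 * realization$n_nodes)
  traj <- integrate_open_loop(realization, params, input, n_train)
  idx <- seq.int(n_listen + 1, n_train + 1)
  times <- traj$times[idx]
  states <- traj$states[idx, , drop = FALSE]
  u <- if (is.function(input)) input(times) else {
    # input given on the half-step grid: take every second column
    t(input)[seq.int(2 * n_listen + 1, 2 * n_train + 1, by = 2), , drop = FALSE]
  }
  list(features = t(quad_features(states)), targets = t(u),
       end_state = traj$states[n_train + 1, ], times = times)
}

#' Echo-state check for a driven reservoir
#'
#' Re-runs the listening stage from a random nonzero initial state and
#' reports the max-norm difference from the zero-start run at `t_listen`.
#' A small value certifies that harvested states are determined by the
#' input history alone, not by the initial condition (the echo-state
#' property). A warning is raised when the difference exceeds `tol`.
#'
#' @param realization a [reservoir_realization()].
#' @param params an [rc_params()].
#' @param input input function or half-step matrix (see
#'   [integrate_open_loop()]).
#' @param config a [train_config()]; only `t_listen` is used.
#' @param seed seed for the alternative initial state (uniform in
#'   \[-1, 1\]^N).
#' @param tol warning threshold (default 1e-6).
#' @return the max-norm state difference at `t_listen` (invisibly a
#'   scalar), with attribute `pass`.
#' @export
echo_state_check <- function(realization, params, input, config, seed = 1,
                             tol = 1e-6) {
  n_listen <- round(config$t_listen / config$tau)
  r_alt <- withr::with_seed(seed,
    stats::runif(realization$n_nodes, -1, 1))
  a <- integrate_open_loop(realization, params, input, n_listen)
  b <- integrate_open_loop(realization, params, input, n_listen, r0 = r_alt)
  d <- max(abs(a$states[n_listen + 1, ] - b$states[n_listen + 1, ]))
  if (d > tol)
    warning(sprintf("echo-state check: state difference %.3g > %.3g at t_listen",
                    d, tol))
  structure(d, pass = d <= tol)
}

#' Ridge-regression readout
#'
#' Solves `W_out = Y X^T (X X^T + beta I)^{-1}` via a Cholesky
#' factorization of the symmetric positive-definite Gram matrix — no
#' explicit inverse is formed.
#'
#' @param features 2N x T matrix X (column-concatenated over tasks).
#' @param targets D x T matrix Y with the same column count.
#' @param ridge_param the ridge penalty beta (>= 0).
#' @return the D x 2N readout matrix.
#' @export
ridge_readout <- function(features, targets, ridge_param) {
  stopifnot(ncol(features) == ncol(targets), ridge_param >= 0)
  G <- tcrossprod(features)
  diag(G) <- diag(G) + ridge_param
  R <- tryCatch(chol(G), error = function(e)
    stop("Gram matrix X X^T + beta I is not positive definite; ",
         "use ridge_param > 0", call. = FALSE))
  # W^T = G^{-1} X Y^T via two triangular solves
  WT <- backsolve(R, backsolve(R, features %*% t(targets), transpose = TRUE))
  t(WT)
}

#' Train one reservoir on the seeing-double task
#'
#' Harvests open-loop responses to both orbit drives independently (same
#' matrices, parameters and training window for both — only the drive
#' differs), concatenates features and targets, solves the ridge
#' regression, and returns the readout together with both end-of-training
#' states, which serve as the canonical initial conditions for testing the
#' closed loop on each orbit.
#'
#' @param realization a [reservoir_realization()].
#' @param params an [rc_params()].
#' @param pair a [task_pair()].
#' @param config a [train_config()].
#' @param features `"quadratic"` (default) or `"linear"` (no squared
#'   features; admits mirror attractors — exposed for symmetry
#'   experiments).
#' @return an object of class `trained_rc`: `realization`, `params`,
#'   `readout` (D x 2N), `end_state_A`, `end_state_B`, `config`, `pair`,
#'   `features`, and the training residual `train_mse`.
#' @export
train_seeing_double <- function(realization, params, pair, config,
                                features = c("quadratic", "linear")) {
  features <- match.arg(features)
  stopifnot(inherits(pair, "task_pair"))
  ha <- harvest(realization, params, orbit_input(pair$orbit_A), config)
  hb <- harvest(realization, params, orbit_input(pair$orbit_B), config)
  X <- cbind(ha$features, hb$features)
  Y <- cbind(ha$targets, hb$targets)
  if (features == "linear") X <- X[seq_len(realization$n_nodes), , drop = FALSE]
  W <- ridge_readout(X, Y, config$ridge_param)
  resid <- W %*% X - Y
  x <- structure(list(realization = realization, params = params,
                      readout = W,
                      end_state_A = ha$end_state, end_state_B = hb$end_state,
                      config = config, pair = pair, features = features,
                      train_mse = mean(resid^2)),
                 class = "trained_rc")
  validate_trained_rc(x)
  x
}

#' Validate the invariants of a trained reservoir
#'
#' Readout entries finite; end states finite with all components within
#' the invariant box (|r_i| <= 1 + 1e-6). Errors on violation.
#'
#' @param x a `trained_rc`.
#' @export
validate_trained_rc <- function(x) {
  stopifnot(inherits(x, "trained_rc"))
  if (!all(is.finite(x$readout))) stop("readout contains non-finite entries")
  for (s in list(x$end_state_A, x$end_state_B)) {
    if (!all(is.finite(s))) stop("end state contains non-finite entries")
    if (max(abs(s)) > 1 + 1e-6)
      stop("end state escapes the invariant box [-1, 1]^N")
  }
  invisible(x)
}

#' @export
print.trained_rc <- function(x, ...) {
  cat(sprintf(
    "<trained_rc> N = %d, rho = %g, x_cen = %g, %s features\n",
    x$realization$n_nodes, x$realization$spectral_radius, x$pair$x_cen,
    x$features))
  cat(sprintf("  readout %d x %d, training MSE %.3g\n",
              nrow(x$readout), ncol(x$readout), x$train_mse))
  invisible(x)
}
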