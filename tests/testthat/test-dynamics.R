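test_that("open-loop derivative has the leaky tanh form", {
  re <- zero_realization(10)
  pr0 <- rc_params(gamma = 3, sigma = 0)
  r0 <- seq(-0.5, 0.4, length.out = 10)
  # M = 0, sigma = 0: pure decay
  expect_equal(open_loop_derivative(r0, c(1, 2), re, pr0), -3 * r0)
  # origin with zero input is a fixed point
  expect_equal(open_loop_derivative(numeric(10), c(0, 0), re, rc_params()),
               numeric(10))
  # M = 0, constant input: r* = tanh(sigma W_in u) is a fixed point
  pr <- rc_params(gamma = 10, sigma = 0.3)
  u <- c(0.7, -1.2)
  rstar <- tanh(0.3 * drop(re$input_weights %*% u))
  expect_equal(open_loop_derivative(rstar, u, re, pr), numeric(10),
               tolerance = 1e-14)
  expect_error(open_loop_derivative(numeric(3), c(0, 0), re, pr), "state")
})

test_that("RK4 reproduces the linear decay solution", {
  re <- zero_realization(4)
  pr <- rc_params(gamma = 10, sigma = 0, tau = 0.01)
  r0 <- c(1, -0.5, 0.25, 0.8)
  traj <- integrate_open_loop(re, pr, zero_input, 100, r0 = r0)
  # RK4 at gamma*tau = 0.1: relative error ~ (gamma*tau)^4
  expect_equal(traj$states[101, ], r0 * exp(-10 * 1), tolerance = 1e-5)
  # n_steps = 0 returns just the initial state
  t0 <- integrate_open_loop(re, pr, zero_input, 0, r0 = r0)
  expect_equal(t0$states, matrix(r0, 1))
  # too-short precomputed input errors
  expect_error(
    integrate_open_loop(re, pr, matrix(0, 2, 5), 10, r0 = r0),
    "too short")
})

test_that("RK4 converges at fourth order on the decay benchmark", {
  re <- zero_realization(1)
  r0 <- 1
  taus <- c(0.05, 0.025, 0.0125, 0.00625)
  errs <- vapply(taus, function(tau) {
    pr <- rc_params(gamma = 10, sigma = 0, tau = tau)
    n <- round(1 / tau)
    traj <- integrate_open_loop(re, pr, zero_input, n, r0 = r0)
    abs(traj$states[n + 1, 1] - exp(-10))
  }, numeric(1))
  slope <- coef(lm(log(errs) ~ log(taus)))[2]
  expect_gt(slope, 3.8)
  expect_lt(slope, 4.2)
})

test_that("open-loop integration is deterministic", {
  re <- reservoir_realization(0.3, seed = 4, n_nodes = 30)
  pr <- rc_params()
  inp <- orbit_input(orbit_spec(6.5))
  a <- integrate_open_loop(re, pr, inp, 500)
  b <- integrate_open_loop(re, pr, inp, 500)
  expect_identical(a$states, b$states)
})

test_that("closed loop with zero readout decays to the origin", {
  re <- zero_realization(6)
  trained <- list(realization = re, params = rc_params(gamma = 10, sigma = 0.1),
                  readout = matrix(0, 2, 12), features = "quadratic")
  r0 <- runif(6, -1, 1)
  run <- integrate_closed_loop(trained, r0, 100, record_states = TRUE)
  expect_equal(run$states[101, ], r0 * exp(-10), tolerance = 1e-5)
  expect_equal(run$projected[50, ], c(0, 0))
})

test_that("closed-loop states are absorbed into the unit box", {
  # the tanh saturation makes [-1,1]^N globally attracting for any readout
  re <- reservoir_realization(0.5, seed = 13, n_nodes = 40)
  pr <- rc_params()
  set.seed(99)
  for (k in 1:5) {
    W <- matrix(rnorm(2 * 80, sd = 2), 2, 80)
    trained <- list(realization = re, params = pr, readout = W,
                    features = "quadratic")
    r0 <- runif(40, -1, 1)
    run <- integrate_closed_loop(trained, r0, 200, record_states = TRUE)
    late <- run$states[run$times >= 1, , drop = FALSE]
    expect_lte(max(abs(late)), 1 + 1e-6)
  }
})

test_that("projection applies the readout to the feature map", {
  expect_equal(project(matrix(rnorm(8), 2, 4), c(0, 0)), c(0, 0))
  # selector readout returns the first two state components
  W <- cbind(diag(2), matrix(0, 2, 4))  # D = 2, N = 3, quadratic
  s <- c(0.3, -0.7, 0.2)
  expect_equal(project(W, s), s[1:2])
  # trained readout reproduces its training targets
  tr <- trained_good()
  expect_lt(tr$train_mse, 1e-2)
  u_hat <- project(tr$readout, tr$end_state_A)
  u_ref <- orbit_point(tr$pair$orbit_A, tr$config$t_train)
  expect_lt(sqrt(sum((u_hat - u_ref)^2)), 0.5)
})
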