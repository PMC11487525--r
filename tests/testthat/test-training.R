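test_that("quadratic feature map appends elementwise squares", {
  expect_equal(quad_features(c(1, -2)), c(1, -2, 1, 4))
  expect_equal(quad_features(numeric(3)), numeric(6))
  # evenness of the squares breaks the odd symmetry
  r <- c(0.4, -0.9)
  expect_false(isTRUE(all.equal(quad_features(-r), -quad_features(r))))
  m <- matrix(1:6, 2, 3)
  expect_equal(quad_features(m), cbind(m, m^2))
})

test_that("training window invariants are enforced", {
  expect_error(train_config(t_listen = 10, t_train = 5), "t_train")
  expect_error(train_config(ridge_param = -1), "ridge_param")
  # harvest refuses a window with fewer columns than the feature dimension
  re <- reservoir_realization(0.2, seed = 3, n_nodes = 100)
  cfg_short <- train_config(t_listen = 0.5, t_train = 1.5)
  expect_error(harvest(re, rc_params(), orbit_input(orbit_spec(8)), cfg_short),
               "2N")
})

test_that("harvest returns features, targets and end state with the contracted shapes", {
  re <- reservoir_realization(0.2, seed = 3, n_nodes = 100)
  pr <- rc_params()
  cfg <- train_config(t_listen = 1, t_train = 4)
  h <- harvest(re, pr, orbit_input(orbit_spec(8)), cfg)
  T_expect <- (4 - 1) / 0.01 + 1
  expect_equal(dim(h$features), c(200, T_expect))
  expect_equal(dim(h$targets), c(2, T_expect))
  expect_equal(unname(h$targets[, 1]),
               unname(orbit_point(orbit_spec(8), 1)[1, ]))
  expect_length(h$end_state, 100)
  # M = 0, sigma = 0: everything decays from the zero start
  re0 <- zero_realization(100)
  h0 <- harvest(re0, rc_params(sigma = 0), zero_input, cfg)
  expect_lt(max(abs(h0$features)), 1e-10)
})

test_that("the listening stage erases the initial condition", {
  re <- reservoir_realization(0.7, seed = 1)
  cfg <- train_config()
  d <- echo_state_check(re, rc_params(), orbit_input(orbit_spec(6.5)), cfg,
                        seed = 8)
  expect_lt(as.numeric(d), 1e-6)
})

test_that("ridge readout matches the closed-form normal equations", {
  # X = I, beta = 0: W = Y
  Y <- matrix(rnorm(8), 2, 4)
  expect_equal(ridge_readout(diag(4), Y, 0), Y, tolerance = 1e-12)
  # against the brute-force oracle
  set.seed(5)
  X <- matrix(rnorm(6 * 40), 6, 40)
  Y <- matrix(rnorm(2 * 40), 2, 40)
  expect_equal(ridge_readout(X, Y, 0.1), ridge_oracle(X, Y, 0.1),
               tolerance = 1e-10)
  # readout norm shrinks with the penalty
  n1 <- norm(ridge_readout(X, Y, 1e6), "F")
  n2 <- norm(ridge_readout(X, Y, 1e8), "F")
  expect_lt(n2, n1)
  # singular Gram matrix without a ridge is refused
  Xs <- matrix(1, 3, 10)
  expect_error(ridge_readout(Xs, matrix(1, 1, 10), 0), "ridge_param > 0")
})

test_that("readout is invariant to the concatenation order of tasks", {
  set.seed(6)
  X1 <- matrix(rnorm(6 * 30), 6, 30); Y1 <- matrix(rnorm(2 * 30), 2, 30)
  X2 <- matrix(rnorm(6 * 30), 6, 30); Y2 <- matrix(rnorm(2 * 30), 2, 30)
  Wab <- ridge_readout(cbind(X1, X2), cbind(Y1, Y2), 0.1)
  Wba <- ridge_readout(cbind(X2, X1), cbind(Y2, Y1), 0.1)
  expect_equal(Wab, Wba, tolerance = 1e-10)
  # and to any column permutation
  perm <- sample(60)
  Wp <- ridge_readout(cbind(X1, X2)[, perm], cbind(Y1, Y2)[, perm], 0.1)
  expect_equal(Wab, Wp, tolerance = 1e-10)
})

test_that("seeing-double training satisfies its output contract", {
  tr <- trained_good()
  expect_equal(dim(tr$readout), c(2, 200))
  expect_true(all(is.finite(tr$readout)))
  expect_lte(max(abs(tr$end_state_A)), 1 + 1e-6)
  expect_lte(max(abs(tr$end_state_B)), 1 + 1e-6)
  expect_lt(tr$train_mse, 1e-2)
  expect_silent(validate_trained_rc(tr))
})
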