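test_that("local maxima use the three-point stencil with plateau handling", {
  t <- seq(0, 8 * pi - 0.01, by = 0.01)
  m <- local_maxima(sin(t))
  expect_length(m, 4)
  expect_true(all(abs(m - 1) < 1e-3))
  expect_length(local_maxima(seq_len(100)), 0)
  xm <- local_maxima(5 * cos(t) + 6.5)
  expect_true(all(abs(xm - 11.5) < 1e-3))
  # plateau start counts once
  expect_equal(local_maxima(c(0, 1, 1, 1, 0, 2, 0)), c(1, 2))
  expect_error(local_maxima(c(1, 2)), "too short")
  # discard removes the leading transient
  s <- c(seq(10, 0, length.out = 50), sin(seq(0, 4 * pi, by = 0.1)))
  expect_true(all(local_maxima(s, discard_fraction = 0.5) < 1.1))
})

test_that("attractor classification labels the canonical cases", {
  pair <- task_pair(6.5)
  t <- seq(0, 20 * pi, by = 0.01)
  const <- matrix(rep(c(1, 2), each = length(t)), ncol = 2)
  expect_equal(classify_attractor(const, t, pair), "fixed_point")
  circA <- cbind(5 * cos(t) + 6.5, 5 * sin(t))
  expect_equal(classify_attractor(circA, t, pair), "orbit_A")
  circB <- cbind(-5 * cos(t) - 6.5, 5 * sin(t))
  expect_equal(classify_attractor(circB, t, pair), "orbit_B")
  # alternating loops about the two centers: switching
  block <- function(cx) cbind(5 * cos(t[1:700]) + cx, 5 * sin(t[1:700]))
  sw <- rbind(block(6.5), block(-6.5), block(6.5), block(-6.5),
              block(6.5), block(-6.5))
  expect_equal(classify_attractor(sw, seq_len(nrow(sw)) * 0.01, pair,
                                  discard_fraction = 0),
               "switching")
})

test_that("a single-step sweep equals the direct train-integrate-extract run", {
  re <- reservoir_realization(0.2, seed = 7)
  pr <- rc_params()
  pair <- task_pair(8)
  cfg <- train_config(20, 120)
  tab <- continuation_sweep(re, pr, pair, 0.2, 0.2, 0.01, cfg, t_track = 50)
  trained <- train_seeing_double(with_spectral_radius(re, 0.2), pr, pair, cfg)
  runA <- integrate_closed_loop(trained, trained$end_state_A, 5000)
  expect_identical(tab$xm[[1]], local_maxima(runA$projected[, 1], 0.5))
  expect_equal(tab$branch_id, c("branch_A", "branch_B"))
  expect_error(
    continuation_sweep(re, pr, pair, 0.3, 0.25, 0.2, cfg, t_track = 50),
    "rho_step")
})

test_that("a short downward sweep tracks both orbits where multifunctional", {
  re <- reservoir_realization(0.2, seed = 7)
  pr <- rc_params()
  pair <- task_pair(8)
  cfg <- train_config(20, 120)
  tab <- continuation_sweep(re, pr, pair, 0.45, 0.41, 0.02, cfg,
                            t_track = 100)
  expect_equal(nrow(tab), 6)
  expect_equal(tab$rho[tab$branch_id == "branch_A"], c(0.45, 0.43, 0.41))
  a <- tab[tab$branch_id == "branch_A", ]
  b <- tab[tab$branch_id == "branch_B", ]
  expect_true(all(a$label == "orbit_A"))
  expect_true(all(b$label == "orbit_B"))
  # x_m clusters at x_cen + b and -x_cen + b
  expect_true(all(abs(unlist(a$xm) - 13) < 0.05 * 13))
  expect_true(all(abs(unlist(b$xm) + 3) < 0.05 * 3))
  # carried states respect the boundedness invariant
  cs <- attr(tab, "carried_states")
  expect_lte(max(abs(unlist(cs))), 1 + 1e-6)
  # determinism
  tab2 <- continuation_sweep(re, pr, pair, 0.45, 0.41, 0.02, cfg,
                             t_track = 100)
  expect_identical(tab$xm, tab2$xm)
  # long format has one row per maximum
  long <- continuation_long(tab)
  expect_equal(nrow(long), sum(tab$n_xm))
  expect_equal(names(long), c("rho", "branch_id", "xm", "label"))
})

test_that("random-state probing classifies every basin deterministically", {
  tr <- trained_good()
  probes <- probe_basins(tr, k = 3, t_probe = 60, seed = 2)
  expect_equal(nrow(probes), 3)
  expect_true(all(probes$label %in%
                    c("orbit_A", "orbit_B", "fixed_point", "switching",
                      "other")))
  expect_identical(probes, probe_basins(tr, k = 3, t_probe = 60, seed = 2))
})
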