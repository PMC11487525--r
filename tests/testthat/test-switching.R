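test_that("non-ideal relay ignores in-band excursions", {
  th <- relay_thresholds(-2, 2)
  # dip to 0 stays inside the band: no transition registered
  tr <- relay_transitions(c(3, 0, 3), 1:3, th)
  expect_equal(tr$initial_state, "B")
  expect_equal(nrow(tr$entries), 0)
  # full crossings alternate
  tr2 <- relay_transitions(c(3, -3, 3, -3), 1:4, th)
  expect_equal(tr2$initial_state, "B")
  expect_equal(tr2$entries$index, c(2, 3, 4))
  expect_equal(tr2$entries$entered_state, c("A", "B", "A"))
  expect_equal(tr2$entries$time, c(2, 3, 4))
  # never-determined series
  tr3 <- relay_transitions(rep(0, 5), 1:5, th)
  expect_equal(tr3$initial_state, "undetermined")
  expect_equal(nrow(tr3$entries), 0)
  # samples exactly at a threshold do not trigger
  tr4 <- relay_transitions(c(3, 2, -2, 3), 1:4, th)
  expect_equal(nrow(tr4$entries), 0)
  # orientation flag swaps the labels
  tr5 <- relay_transitions(c(3, -3), 1:2, th, high_state = "A")
  expect_equal(tr5$initial_state, "A")
  expect_equal(tr5$entries$entered_state, "B")
})

test_that("relay output is invariant under side-preserving perturbations", {
  th <- relay_thresholds(-2, 2)
  set.seed(12)
  for (k in 1:50) {
    x <- runif(200, -4, 4)
    base <- relay_transitions(x, seq_along(x), th)
    pert <- x
    hi <- x > 2; lo <- x < -2; mid <- !hi & !lo
    pert[hi] <- x[hi] + runif(sum(hi))
    pert[lo] <- x[lo] - runif(sum(lo))
    pert[mid] <- x[mid] * runif(sum(mid))  # shrinks toward 0, stays in band
    after <- relay_transitions(pert, seq_along(x), th)
    expect_identical(base$entries, after$entries)
    expect_identical(base$initial_state, after$initial_state)
  }
})

test_that("relay detection is causal", {
  th <- relay_thresholds(-2, 2)
  set.seed(30)
  for (k in 1:20) {
    x <- runif(100, -4, 4)
    full <- relay_transitions(x, seq_along(x), th)
    cut <- sample(10:90, 1)
    part <- relay_transitions(x[1:cut], 1:cut, th)
    expect_identical(part$entries,
                     full$entries[full$entries$index <= cut, ],
                     ignore_attr = TRUE)
  }
})

test_that("residence durations cover completed stays only", {
  th <- relay_thresholds(-2, 2)
  mk <- function(times, states) {
    structure(list(entries = data.frame(time = times, entered_state = states,
                                        index = seq_along(times)),
                   initial_state = "undetermined"),
              class = "transition_sequence")
  }
  d <- residence_durations(mk(c(10, 25, 30), c("A", "B", "A")))
  expect_equal(d$durations_A, 15)
  expect_equal(d$durations_B, 5)
  single <- residence_durations(mk(20, "A"))
  expect_length(single$durations_A, 0)
  expect_length(single$durations_B, 0)
  # conservation: completed stays partition the span between first and last
  times <- cumsum(runif(9, 1, 10))
  states <- rep(c("A", "B"), length.out = 9)
  dd <- residence_durations(mk(times, states))
  expect_equal(sum(dd$durations_A) + sum(dd$durations_B),
               times[9] - times[1])
})

test_that("log-binned density normalizes and rejects degenerate input", {
  set.seed(77)
  d <- rlnorm(500)
  h <- log_binned_density(d, 40)
  expect_equal(sum(h$density * diff(h$bin_edges)), 1, tolerance = 1e-12)
  expect_equal(sum(h$counts), 500)
  expect_error(log_binned_density(c(1, 1, 1)), "degenerate")
  expect_error(log_binned_density(numeric(0)), "positive")
})

test_that("chunked switching collection equals one long integration", {
  tr <- trained_switching()
  th <- relay_thresholds()
  long <- integrate_closed_loop(tr, tr$end_state_A, 60000)
  ref <- relay_transitions(long$projected[, 1], long$times, th,
                           high_state = "A")
  ch <- collect_switchings(tr, tr$end_state_A, target_count = 10^9,
                           thresholds = th, max_time = 600,
                           chunk_time = 137)
  expect_gt(nrow(ref$entries), 4)  # this instance does switch
  expect_identical(ch$entries$time, ref$entries$time)
  expect_identical(ch$entries$index, ref$entries$index)
  expect_identical(ch$entries$entered_state, ref$entries$entered_state)
  expect_false(ch$complete)
  # alternation and strict time-ordering (type invariant)
  expect_true(all(diff(ch$entries$time) > 0))
  expect_true(all(ch$entries$entered_state[-1] !=
                    ch$entries$entered_state[-nrow(ch$entries)]))
  # a multifunctional closed loop produces no transitions: flagged partial
  quiet <- collect_switchings(trained_good(), trained_good()$end_state_A,
                              target_count = 1, thresholds = th,
                              max_time = 30)
  expect_equal(nrow(quiet$entries), 0)
  expect_false(quiet$complete)
})

test_that("escape time is the first departure from the starting state", {
  th <- relay_thresholds(-2, 2)
  times <- seq(0, 300, by = 1)
  x <- c(rep(5, 191), rep(-3, 110))
  expect_equal(escape_time(x, times, th, start_state = "A"), 191)
  expect_true(is.na(escape_time(rep(5, 301), times, th, start_state = "A")))
  # definitional consistency with the transition list
  set.seed(3)
  y <- c(5, runif(200, -4, 4))
  tr <- relay_transitions(y, seq_along(y), th, high_state = "A")
  first_out <- tr$entries$time[tr$entries$entered_state != "A"][1]
  expect_equal(escape_time(y, seq_along(y), th, start_state = "A"),
               first_out - 1)
})

test_that("winding counts tag completed stays with their loop numbers", {
  pair <- task_pair(6.5)
  loop <- function(spec, from, to, n) orbit_point(spec, seq(from, to, length.out = n))
  pts <- rbind(
    loop(pair$orbit_A, 0, pi / 2, 50),        # initial partial stay in A
    loop(pair$orbit_B, 0, 2 * pi, 200),       # one full loop about B
    loop(pair$orbit_A, 0, 4 * pi, 400),       # two full loops about A
    loop(pair$orbit_B, 0, pi / 2, 50))        # final partial stay
  times <- (seq_len(nrow(pts)) - 1) * 0.01
  tr <- relay_transitions(pts[, 1], times, relay_thresholds(),
                          high_state = "A")
  w <- residence_windings(tr, pts, pair)
  expect_equal(w$state, c("B", "A"))
  expect_equal(w$windings, c(1, 2))
})

test_that("escape times grow as rho approaches restabilization", {
  # instance with one unstable reconstructed orbit: the escape time climbs
  # a staircase toward the rho at which the orbit regains stability
  re <- reservoir_realization(0.7, seed = 1)
  es <- escape_time_sweep(re, rc_params(), task_pair(6.5),
                          seq(0.325, 0.405, by = 0.016), train_config(),
                          relay_thresholds(), horizon = 300, branch = "B")
  expect_true(all(es$escaped))
  steps <- diff(es$t_esc)
  expect_gte(mean(steps >= 0), 0.8)
  expect_gt(es$t_esc[nrow(es)], es$t_esc[1])
  # reproducibility
  es2 <- escape_time_sweep(re, rc_params(), task_pair(6.5),
                           seq(0.325, 0.405, by = 0.016), train_config(),
                           relay_thresholds(), horizon = 300, branch = "B")
  expect_identical(es$t_esc, es2$t_esc)
})
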