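#' One circular orbit of the seeing-double task
#'
#' The driving signal `u(t) = (bx cos t + x_center, by sin t)` traces a
#' circle of radius `b = |bx| = |by|` centered at `(x_center, 0)`. The signs
#' of `bx`, `by` set the rotation direction: `bx = by` is counter-clockwise,
#' `bx = -by` clockwise.
#'
#' @param x_center signed center offset along the x-axis.
#' @param bx,by signed radii; must satisfy |bx| = |by| > 0.
#' @return an object of class `orbit_spec`.
#' @export
orbit_spec <- function(x_center, bx = 5, by = 5) {
  if (abs(bx) != abs(by) || abs(bx) <= 0)
    stop("orbit requires |bx| = |by| > 0")
  structure(list(x_center = x_center, bx = bx, by = by, b = abs(bx)),
            class = "orbit_spec")
}

#' The two orbits of a seeing-double task
#'
#' Orbit A is counter-clockwise, radius `b`, centered at `(+x_cen, 0)`;
#' orbit B is its reflection through the y-axis: clockwise (`bx = -b`),
#' centered at `(-x_cen, 0)`. Decreasing `x_cen` moves the circles
#' together; they touch at `x_cen = b` and overlap for `0 < x_cen < b`.
#'
#' @param x_cen non-negative center offset magnitude.
#' @param b orbit radius (default 5).
#' @return an object of class `task_pair` with elements `orbit_A`,
#'   `orbit_B`, `x_cen`, `b`.
#' @export
task_pair <- function(x_cen, b = 5) {
  stopifnot(x_cen >= 0, b > 0)
  structure(list(orbit_A = orbit_spec(+x_cen, b, b),
                 orbit_B = orbit_spec(-x_cen, -b, b),
                 x_cen = x_cen, b = b),
            class = "task_pair")
}

#' Evaluate an orbit's driving signal at arbitrary times
#'
#' Returns the exact analytic value of `u(t)`; used directly by the RK4
#' integrator at half-step times, avoiding interpolation error.
#'
#' @param spec an [orbit_spec()].
#' @param t numeric vector of times.
#' @return a length(t) x 2 matrix with columns x, y.
#' @export
orbit_point <- function(spec, t) {
  cbind(x = spec$bx * cos(t) + spec$x_center, y = spec$by * sin(t))
}

#' Input function of an orbit (closure over time)
#'
#' @param spec an [orbit_spec()].
#' @return a function `f(t)` returning a length(t) x 2 matrix.
#' @export
orbit_input <- function(spec) {
  force(spec)
  function(t) orbit_point(spec, t)
}

#' Sample an orbit's driving signal on a regular time grid
#'
#' @param spec an [orbit_spec()].
#' @param n_samples number of samples.
#' @param tau sampling step (default 0.01).
#' @param t_start first sample time.
#' @return a `planar_trajectory`: list with `times` and `points`
#'   (n_samples x 2).
#' @export
orbit_signal <- function(spec, n_samples, tau = 0.01, t_start = 0) {
  stopifnot(tau > 0, n_samples >= 1)
  times <- t_start + (seq_len(n_samples) - 1) * tau
  structure(list(times = times, points = orbit_point(spec, times)),
            class = "planar_trajectory")
}

#' Geometric relation between the two orbits
#'
#' @param x_cen_magnitude |x_cen| >= 0.
#' @param b orbit radius > 0.
#' @return one of `"disjoint"` (|x_cen| > b), `"touching"` (= b),
#'   `"overlapping"` (0 < |x_cen| < b), `"identical"` (x_cen = 0).
#' @export
overlap_class <- function(x_cen_magnitude, b) {
  stopifnot(x_cen_magnitude >= 0, b > 0)
  if (x_cen_magnitude == 0) "identical"
  else if (x_cen_magnitude < b) "overlapping"
  else if (x_cen_magnitude == b) "touching"
  else "disjoint"
}

#' Mean relative radial deviation of a planar trajectory from an orbit
#'
#' After discarding an initial transient, the mean over retained points of
#' `|dist(point, center) - b| / b`. Zero for exact samples of the circle;
#' 1 for a trajectory collapsed onto the center.
#'
#' @param traj a `planar_trajectory` or a T x 2 matrix of points.
#' @param spec the reference [orbit_spec()].
#' @param discard_fraction fraction of leading points dropped as transient.
#' @return a non-negative scalar.
#' @export
radial_error <- function(traj, spec, discard_fraction = 0.5) {
  pts <- if (inherits(traj, "planar_trajectory")) traj$points else
    if (inherits(traj, "closed_loop_trajectory")) traj$projected else traj
  stopifnot(discard_fraction >= 0, discard_fraction < 1)
  keep <- seq.int(floor(nrow(pts) * discard_fraction) + 1, nrow(pts))
  if (length(keep) < 1) stop("no points retained after transient discard")
  d <- sqrt((pts[keep, 1] - spec$x_center)^2 + pts[keep, 2]^2)
  mean(abs(d - spec$b)) / spec$b
}

#' Net rotation direction of a planar trajectory about a center
#'
#' Sign of the summed cross products of successive center-relative
#' displacements: +1 counter-clockwise, -1 clockwise, 0 indeterminate
#' (|sum| below `tol * n`).
#'
#' @param traj a `planar_trajectory`, `closed_loop_trajectory`, or T x 2
#'   matrix (T >= 3).
#' @param center length-2 center point.
#' @param tol per-point tolerance for the indeterminate verdict.
#' @return -1, 0 or +1.
#' @export
rotation_direction <- function(traj, center, tol = 1e-9) {
  pts <- if (inherits(traj, "planar_trajectory")) traj$points else
    if (inherits(traj, "closed_loop_trajectory")) traj$projected else traj
  if (nrow(pts) < 3) stop("need at least 3 points")
  dx <- pts[, 1] - center[1]
  dy <- pts[, 2] - center[2]
  n <- nrow(pts)
  s <- sum(dx[-n] * dy[-1] - dy[-n] * dx[-1])
  if (abs(s) < tol * n) 0 else sign(s)
}

#' Test a trained reservoir for multifunctionality
#'
#' Integrates the closed loop from each orbit's end-of-training state for
#' `horizon` time units and scores each projected trajectory against its
#' target orbit: the reconstruction passes if, after discarding the first
#' `discard_fraction` of the run, the mean relative radial deviation is
#' below `tol` and the net rotation direction matches the orbit
#' (counter-clockwise for A, clockwise for B).
#'
#' Verdicts: `"multifunctional"` if both reconstructions pass, `"partial"`
#' if exactly one does (e.g. both initializations fall onto the same stable
#' orbit), `"failed"` if neither does (e.g. the switching regime, where the
#' state wanders across both orbit regions).
#'
#' @param trained a `trained_rc` from [train_seeing_double()].
#' @param pair the [task_pair()]; defaults to the one stored at training.
#' @param horizon integration time for each test run (default 500, about 80
#'   orbit periods — long enough to expose slow escapes from unstable
#'   orbits).
#' @param tol radial-error threshold (default 0.05, i.e. 5% of the radius).
#' @param discard_fraction leading fraction discarded as transient.
#' @return a list with `verdict` and a per-orbit `diagnostics` data frame
#'   (radial error, rotation direction, pass flag).
#' @export
multifunctionality_check <- function(trained, pair = trained$pair,
                                     horizon = 500, tol = 0.05,
                                     discard_fraction = 0.5) {
  stopifnot(inherits(pair, "task_pair"))
  n_steps <- round(horizon / trained$params$tau)
  score <- function(r0, spec, want_dir) {
    run <- integrate_closed_loop(trained, r0, n_steps)
    err <- radial_error(run$projected, spec, discard_fraction)
    keep <- seq.int(floor(nrow(run$projected) * discard_fraction) + 1,
                    nrow(run$projected))
    dir <- rotation_direction(run$projected[keep, , drop = FALSE],
                              c(spec$x_center, 0))
    list(radial_error = err, direction = dir,
         pass = err < tol && dir == want_dir)
  }
  a <- score(trained$end_state_A, pair$orbit_A, +1)
  b <- score(trained$end_state_B, pair$orbit_B, -1)
  n_pass <- a$pass + b$pass
  verdict <- c("failed", "partial", "multifunctional")[n_pass + 1]
  diagnostics <- data.frame(
    orbit = c("A", "B"),
    radial_error = c(a$radial_error, b$radial_error),
    direction = c(a$direction, b$direction),
    expected_direction = c(1, -1),
    pass = c(a$pass, b$pass))
  list(verdict = verdict, diagnostics = diagnostics)
}
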