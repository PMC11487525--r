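#' Serialize a reservoir realization or trained reservoir to one archive
#'
#' Single-file archive (RDS) holding the matrices, parameters and seed;
#' numeric content round-trips bit-exactly.
#'
#' @param x a `reservoir_realization` or `trained_rc`.
#' @param path output file path.
#' @export
write_archive <- function(x, path) {
  stopifnot(inherits(x, "reservoir_realization") ||
              inherits(x, "trained_rc"))
  saveRDS(x, path)
  invisible(path)
}

#' @rdname write_archive
#' @return `read_archive` returns the stored object with its class intact.
#' @export
read_archive <- function(path) {
  x <- readRDS(path)
  if (inherits(x, "reservoir_realization")) validate_realization(x)
  if (inherits(x, "trained_rc")) validate_trained_rc(x)
  x
}

#' Write a trajectory as columnar text
#'
#' CSV with a `t` column followed by one column per state component
#' (`r_1 ... r_N` for reservoir states, `x, y` for planar trajectories).
#' Values are written with full double precision (17 significant digits),
#' so the round-trip through [read_trajectory_csv()] is exact to the
#' representation.
#'
#' @param traj a `state_trajectory`, `closed_loop_trajectory` (its
#'   projection is written), or `planar_trajectory`.
#' @param path output path.
#' @export
write_trajectory_csv <- function(traj, path) {
  m <- if (inherits(traj, "state_trajectory")) traj$states
  else if (inherits(traj, "closed_loop_trajectory")) traj$projected
  else if (inherits(traj, "planar_trajectory")) traj$points
  else stop("unsupported trajectory class")
  cols <- if (ncol(m) == 2) c("x", "y") else paste0("r_", seq_len(ncol(m)))
  df <- data.frame(t = traj$times, m)
  names(df) <- c("t", cols)
  old <- options(digits = 17); on.exit(options(old))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @return `read_trajectory_csv` returns a list with `times` and a matrix
#'   `values`.
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  list(times = df$t, values = as.matrix(df[, -1, drop = FALSE]))
}
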