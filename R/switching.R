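#' Thresholds of the two-threshold (non-ideal relay) detector
#'
#' The hysteresis band. Defaults alpha = -2, beta = 2: a switch between the
#' metastable states is registered only when the monitored scalar crosses
#' the *far* threshold, so brief dips into the band never count as
#' transitions (the false alarms a single-threshold detector would emit).
#'
#' @param alpha lower threshold.
#' @param beta upper threshold (> alpha). Named `beta_thr` in the object to
#'   avoid any confusion with the ridge penalty.
#' @return an object of class `relay_thresholds`.
#' @export
relay_thresholds <- function(alpha = -2, beta = 2) {
  stopifnot(alpha < beta)
  structure(list(alpha = alpha, beta_thr = beta), class = "relay_thresholds")
}

state_labels <- function(high_state) {
  high_state <- match.arg(high_state, c("B", "A"))
  if (high_state == "B") c(low = "A", high = "B") else c(low = "B", high = "A")
}

#' Detect transitions with a non-ideal relay
#'
#' Hysteresis semantics: the detector enters the *low* state at the first
#' sample strictly below `alpha` while in the high (or undetermined) state,
#' and enters the *high* state at the first sample strictly above `beta`
#' while in the low (or undetermined) state. Samples inside `[alpha, beta]`
#' never change the state; samples exactly at a threshold do not trigger.
#' The initial state is set by the first threshold crossing (which is not
#' itself a transition).
#'
#' `high_state` names which metastable label is attached to the high side.
#' The default `"B"` assigns the low state to "A". When monitoring the
#' projected x-component of a seeing-double reservoir, pass
#' `high_state = "A"` so the labels match the orbit centers (orbit A is
#' centered at +x_cen): this is what all the domain-level callers in this
#' package do.
#'
#' @param x numeric series of the monitored scalar.
#' @param times matching time stamps (strictly increasing).
#' @param thresholds a [relay_thresholds()].
#' @param high_state `"B"` (default) or `"A"`: label of the high state.
#' @param initial_state carried-in detector state: `"undetermined"`
#'   (default), `"A"` or `"B"`; used when processing a long run in chunks.
#' @return an object of class `transition_sequence`: a list with `entries`
#'   (data.frame of `time`, `entered_state`, `index`), `initial_state`, and
#'   `final_state` (for chunked continuation).
#' @export
relay_transitions <- function(x, times, thresholds,
                              high_state = c("B", "A"),
                              initial_state = "undetermined") {
  stopifnot(length(x) == length(times),
            inherits(thresholds, "relay_thresholds"))
  lab <- state_labels(high_state)
  # symbolic series: +1 above beta, -1 below alpha, NA inside the band
  s <- rep(NA_integer_, length(x))
  s[x > thresholds$beta_thr] <- 1L
  s[x < thresholds$alpha] <- -1L
  carry <- if (identical(initial_state, "undetermined")) NA_integer_
           else if (initial_state == lab[["high"]]) 1L else -1L
  known <- !is.na(s)
  if (!any(known)) {
    entries <- data.frame(time = numeric(0), entered_state = character(0),
                          index = integer(0))
    st <- if (is.na(carry)) "undetermined"
          else if (carry == 1L) lab[["high"]] else lab[["low"]]
    return(structure(list(entries = entries, initial_state = st,
                          final_state = st),
                     class = "transition_sequence"))
  }
  # fill the in-band samples forward with the last determined state
  vals <- s[known]
  filled <- c(carry, vals)[cumsum(known) + 1L]
  first_known <- which(known)[1]
  init <- if (!is.na(carry)) carry else vals[1]
  prev <- c(if (is.na(carry)) NA_integer_ else carry,
            filled[-length(filled)])
  is_entry <- !is.na(filled) & !is.na(prev) & filled != prev
  if (is.na(carry)) {
    # the first determination is initial-state detection, not a transition
    is_entry[seq_len(first_known)] <- FALSE
  }
  idx <- which(is_entry)
  entries <- data.frame(
    time = times[idx],
    entered_state = unname(c(lab[["low"]], lab[["high"]])[(filled[idx] == 1L) + 1L]),
    index = idx)
  init_lab <- if (init == 1L) lab[["high"]] else lab[["low"]]
  final <- filled[length(filled)]
  final_lab <- if (is.na(final)) "undetermined"
               else if (final == 1L) lab[["high"]] else lab[["low"]]
  structure(list(entries = entries, initial_state = init_lab,
                 final_state = final_lab),
            class = "transition_sequence")
}

#' @export
print.transition_sequence <- function(x, ...) {
  cat(sprintf("<transition_sequence> %d transitions, initial state %s\n",
              nrow(x$entries), x$initial_state))
  invisible(x)
}

#' Completed residence durations per metastable state
#'
#' The duration of each *completed* stay — between consecutive transitions.
#' The open-ended stays before the first and after the last transition are
#' excluded.
#'
#' @param transitions a `transition_sequence`.
#' @return a list with numeric vectors `durations_A` and `durations_B`.
#' @export
residence_durations <- function(transitions) {
  stopifnot(inherits(transitions, "transition_sequence"))
  e <- transitions$entries
  if (nrow(e) < 2)
    return(list(durations_A = numeric(0), durations_B = numeric(0)))
  dur <- diff(e$time)
  st <- e$entered_state[-nrow(e)]  # state occupied during each stay
  list(durations_A = dur[st == "A"], durations_B = dur[st == "B"])
}

#' Log-binned probability density of residence times
#'
#' Histogram over `n_bins` bins whose edges are spaced evenly on a log
#' scale between the minimum and maximum of the data, normalized so that
#' `sum(density * bin_width) = 1`.
#'
#' @param durations positive durations (at least 2 distinct values).
#' @param n_bins number of bins (>= 2; default 100).
#' @return an object of class `residence_histogram`: `bin_edges`
#'   (length n_bins + 1), `counts`, `density`, `mids` (geometric bin
#'   midpoints).
#' @export
log_binned_density <- function(durations, n_bins = 100) {
  stopifnot(n_bins >= 2)
  durations <- durations[is.finite(durations)]
  if (length(durations) < 2 || any(durations <= 0))
    stop("need at least 2 positive durations")
  lo <- min(durations); hi <- max(durations)
  if (lo == hi) stop("all durations equal: log-spaced binning is degenerate")
  edges <- exp(seq(log(lo), log(hi), length.out = n_bins + 1))
  edges[1] <- lo; edges[n_bins + 1] <- hi  # guard rounding at the ends
  counts <- graphics::hist(durations, breaks = edges, plot = FALSE,
                           include.lowest = TRUE, right = TRUE)$counts
  widths <- diff(edges)
  density <- counts / (sum(counts) * widths)
  structure(list(bin_edges = edges, counts = counts, density = density,
                 mids = sqrt(edges[-1] * edges[-(n_bins + 1)])),
            class = "residence_histogram")
}

#' Integrate a closed loop until enough transitions are collected
#'
#' Runs the closed loop in chunks, feeding the projected x-component
#' through the relay with carried detector state, until `target_count`
#' transitions are detected or `max_time` is reached. Chunked processing is
#' exact: transition times are identical to those of one long integration.
#'
#' @param trained a `trained_rc`.
#' @param r0 initial state (e.g. `trained$end_state_A`).
#' @param target_count number of transitions wanted.
#' @param thresholds a [relay_thresholds()].
#' @param max_time wall on total integrated time.
#' @param chunk_time integration time per chunk.
#' @param high_state relay orientation; `"A"` (default here) matches the
#'   orbit-center signs of the seeing-double task.
#' @return a `transition_sequence` with extra fields `total_time` and
#'   `complete` (FALSE if `max_time` was hit first — partial result).
#' @export
collect_switchings <- function(trained, r0, target_count, thresholds,
                               max_time, chunk_time = 500,
                               high_state = c("A", "B")) {
  high_state <- match.arg(high_state)
  tau <- trained$params$tau
  chunk_steps <- max(1L, as.integer(round(chunk_time / tau)))
  max_steps <- as.integer(round(max_time / tau))
  entries <- list()
  n_found <- 0L
  step0 <- 0L
  state <- r0
  detector <- "undetermined"
  initial_state <- NULL
  while (step0 < max_steps && n_found < target_count) {
    n_do <- as.integer(min(chunk_steps, max_steps - step0))
    run <- integrate_closed_loop(trained, state, n_do)
    # drop the first sample of every chunk after the first: it duplicates
    # the previous chunk's last sample
    sel <- if (step0 == 0L) seq_len(n_do + 1) else seq.int(2, n_do + 1)
    times <- (step0 + sel - 1L) * tau
    tr <- relay_transitions(run$projected[sel, 1], times, thresholds,
                            high_state = high_state,
                            initial_state = detector)
    if (is.null(initial_state)) initial_state <- tr$initial_state
    detector <- if (tr$final_state == "undetermined") detector else
      tr$final_state
    if (nrow(tr$entries) > 0) {
      # map chunk-local sample positions to indices into the deduplicated
      # concatenated series (chunk k > 0 drops its first, duplicate, sample)
      tr$entries$index <- tr$entries$index +
        (if (step0 == 0L) 0L else step0 + 1L)
      entries[[length(entries) + 1]] <- tr$entries
      n_found <- n_found + nrow(tr$entries)
    }
    state <- run$final_state
    step0 <- step0 + n_do
  }
  entries <- if (length(entries)) do.call(rbind, entries) else
    data.frame(time = numeric(0), entered_state = character(0),
               index = integer(0))
  structure(list(entries = entries,
                 initial_state = if (is.null(initial_state)) "undetermined"
                                 else initial_state,
                 final_state = detector,
                 total_time = step0 * tau,
                 total_steps = step0,
                 final_reservoir_state = state,  # resume a collection here
                 complete = n_found >= target_count),
            class = "transition_sequence")
}

#' Escape time from a metastable state
#'
#' Time of the first relay transition out of `start_state`, measured from
#' `times[1]`. The detector is initialized *in* `start_state` (the caller
#' asserts the run begins there, e.g. when started from the end-of-training
#' state of orbit A).
#'
#' @param x monitored scalar series (projected x-component).
#' @param times matching times.
#' @param thresholds a [relay_thresholds()].
#' @param start_state `"A"` or `"B"`.
#' @param high_state relay orientation (default `"A"` = high, matching the
#'   orbit centers).
#' @return the escape time (scalar), or `NA` if the series never leaves
#'   `start_state`.
#' @export
escape_time <- function(x, times, thresholds, start_state,
                        high_state = c("A", "B")) {
  high_state <- match.arg(high_state)
  stopifnot(start_state %in% c("A", "B"))
  tr <- relay_transitions(x, times, thresholds, high_state = high_state,
                          initial_state = start_state)
  out <- tr$entries[tr$entries$entered_state != start_state, , drop = FALSE]
  if (nrow(out) == 0) NA_real_ else out$time[1] - times[1]
}

#' Escape times across a spectral-radius grid
#'
#' For each rho in `rho_grid`: rescale the base realization, retrain on the
#' task, integrate the closed loop from the orbit-A end-of-training state,
#' and record the escape time from metastable state A (or `NA` if it never
#' escapes within `horizon`). On a realization whose reconstructed orbit A
#' is unstable over the grid, the escape time grows in a staircase-like
#' fashion as rho approaches the restabilization point.
#'
#' @param realization a [reservoir_realization()] (any stored rho).
#' @param params an [rc_params()].
#' @param pair a [task_pair()].
#' @param rho_grid numeric vector of spectral radii.
#' @param config a [train_config()].
#' @param thresholds a [relay_thresholds()].
#' @param horizon integration time per rho.
#' @param branch which orbit's end-of-training state to start from (and
#'   hence which metastable state the escape is measured out of).
#' @return a data.frame with columns `rho`, `t_esc` (NA = not escaped),
#'   `escaped`.
#' @export
escape_time_sweep <- function(realization, params, pair, rho_grid, config,
                              thresholds = relay_thresholds(),
                              horizon = 500, branch = c("A", "B")) {
  branch <- match.arg(branch)
  n_steps <- round(horizon / params$tau)
  res <- lapply(rho_grid, function(rho) {
    trained <- train_seeing_double(with_spectral_radius(realization, rho),
                                   params, pair, config)
    r0 <- if (branch == "A") trained$end_state_A else trained$end_state_B
    run <- integrate_closed_loop(trained, r0, n_steps)
    te <- escape_time(run$projected[, 1], run$times, thresholds,
                      start_state = branch)
    data.frame(rho = rho, t_esc = te, escaped = !is.na(te))
  })
  do.call(rbind, res)
}

#' Winding counts of completed stays
#'
#' Tags each completed residence with the number of full revolutions the
#' projected trajectory makes about the resident orbit's center, computed
#' from the accumulated polar angle. Residence-time histogram branches
#' correspond to different loop counts, so stratifying by this tag
#' decomposes the multi-branch distributions.
#'
#' @param transitions a `transition_sequence` whose `entries$index` refer
#'   to rows of `projected`.
#' @param projected T x 2 matrix of projected states.
#' @param pair the [task_pair()].
#' @return a data.frame with one row per completed stay: `state`,
#'   `duration`, `windings`.
#' @export
residence_windings <- function(transitions, projected, pair) {
  e <- transitions$entries
  if (nrow(e) < 2)
    return(data.frame(state = character(0), duration = numeric(0),
                      windings = integer(0)))
  out <- lapply(seq_len(nrow(e) - 1), function(i) {
    st <- e$entered_state[i]
    center <- if (st == "A") c(pair$x_cen, 0) else c(-pair$x_cen, 0)
    seg <- projected[e$index[i]:e$index[i + 1], , drop = FALSE]
    ang <- atan2(seg[, 2] - center[2], seg[, 1] - center[1])
    total <- sum(abs(diff(ang) - 2 * pi * round(diff(ang) / (2 * pi))))
    data.frame(state = st, duration = e$time[i + 1] - e$time[i],
               windings = as.integer(floor(total / (2 * pi))))
  })
  do.call(rbind, out)
}
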