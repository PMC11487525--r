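#' Full study configuration
#'
#' Validated bundle of every parameter of the seeing-double study: network
#' generation, dynamics, training, the x_cen list, the continuation grid,
#' and the relay thresholds. Unknown arguments are rejected; every field is
#' checked against its type's invariants before any computation runs.
#'
#' @param seed integer seed fixing the random realization.
#' @param n_nodes,connection_prob network parameters.
#' @param gamma,sigma,tau dynamics parameters (see [rc_params()]).
#' @param t_listen,t_train,ridge_param training window and ridge penalty
#'   (see [train_config()]).
#' @param x_cen_values center offsets to study.
#' @param rho_start,rho_end,rho_step continuation grid.
#' @param alpha,beta relay thresholds.
#' @param t_track tracking window per continuation step.
#' @param horizon,tol multifunctionality-verdict parameters.
#' @return an object of class `experiment_config` (a validated named list).
#' @export
experiment_config <- function(seed = 1,
                              n_nodes = 100, connection_prob = 0.04,
                              gamma = 10, sigma = 0.1, tau = 0.01,
                              t_listen = 50, t_train = 550,
                              ridge_param = 1e-4,
                              x_cen_values = c(8.0, 6.5, 5.0, 3.5, 2.0),
                              rho_start = 0.7, rho_end = 0.1,
                              rho_step = 0.01,
                              alpha = -2, beta = 2,
                              t_track = 200, horizon = 500, tol = 0.05) {
  cfg <- structure(list(
    seed = as.integer(seed), n_nodes = as.integer(n_nodes),
    connection_prob = connection_prob, gamma = gamma, sigma = sigma,
    tau = tau, t_listen = t_listen, t_train = t_train,
    ridge_param = ridge_param, x_cen_values = x_cen_values,
    rho_start = rho_start, rho_end = rho_end, rho_step = rho_step,
    alpha = alpha, beta = beta, t_track = t_track, horizon = horizon,
    tol = tol), class = "experiment_config")
  validate_config(cfg)
  cfg
}

config_fields <- function() names(formals(experiment_config))

#' Validate an experiment configuration
#'
#' Delegates each parameter group to its type constructor so every
#' invariant (tau * gamma < 1, alpha < beta, rho ordering, ...) is checked
#' in one place. Errors name the offending field group.
#'
#' @param cfg an `experiment_config`.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  missing <- setdiff(config_fields(), names(cfg))
  if (length(missing))
    stop("config missing required fields: ", paste(missing, collapse = ", "))
  rc_params(cfg$gamma, cfg$sigma, cfg$tau)
  train_config(cfg$t_listen, cfg$t_train, cfg$ridge_param, cfg$tau)
  relay_thresholds(cfg$alpha, cfg$beta)
  stopifnot(cfg$n_nodes >= 1, cfg$connection_prob > 0,
            cfg$connection_prob <= 1, all(cfg$x_cen_values >= 0),
            cfg$rho_start >= cfg$rho_end, cfg$rho_end > 0,
            cfg$rho_step > 0, cfg$t_track > 0, cfg$horizon > 0,
            cfg$tol > 0)
  invisible(cfg)
}

#' Read a study configuration from JSON
#'
#' Strict schema: every field of [experiment_config()] must be present
#' (missing fields are named in the error) and unknown keys are rejected.
#'
#' @param path path to a JSON file.
#' @return an `experiment_config`.
#' @export
load_config <- function(path) {
  raw <- jsonlite::fromJSON(path)
  unknown <- setdiff(names(raw), config_fields())
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  missing <- setdiff(config_fields(), names(raw))
  if (length(missing))
    stop("config missing required fields: ", paste(missing, collapse = ", "))
  do.call(experiment_config, raw)
}

#' Write a study configuration to JSON
#'
#' Round-trips through [load_config()] exactly.
#'
#' @param cfg an `experiment_config`.
#' @param path output path.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

study_sidecar <- function(cfg, extra = list()) {
  c(list(package = "rcswitch",
         version = as.character(utils::packageVersion("rcswitch")),
         seed = cfg$seed,
         config = unclass(cfg),
         config_hash = config_hash(cfg)),
    extra)
}

config_hash <- function(cfg) {
  # small stable fingerprint: sum of a rolling hash over the serialized text
  txt <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  h <- 0
  for (ch in utf8ToInt(as.character(txt))) h <- (h * 31 + ch) %% 2^31
  sprintf("%08x", h)
}

#' Run the full seeing-double study
#'
#' For each `x_cen` in the configuration: trains at `rho_start`, records
#' the multifunctionality verdict, runs the downward continuation sweep,
#' writes the long-format bifurcation CSV (`rho, branch_id, xm, label`),
#' and — wherever the sweep finds a switching label — collects relay
#' transitions at the median switching rho and writes the transition log
#' and, when there are enough completed stays, the log-binned
#' residence-time histogram. Every CSV gets a JSON sidecar carrying the
#' package version, seed, full configuration and a config hash. The run is
#' deterministic given the configuration.
#'
#' @param cfg an [experiment_config()].
#' @param out_dir output directory (created if needed).
#' @param switching_time integration time for the switching collection at
#'   each switching rho (default 2000).
#' @return (invisibly) a summary data.frame with one row per x_cen:
#'   verdict at rho_start, number of switching rho values, paths written.
#' @export
run_study <- function(cfg, out_dir, switching_time = 2000) {
  validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  realization <- reservoir_realization(cfg$rho_start, cfg$seed,
                                       n_nodes = cfg$n_nodes,
                                       connection_prob = cfg$connection_prob)
  params <- rc_params(cfg$gamma, cfg$sigma, cfg$tau)
  config <- train_config(cfg$t_listen, cfg$t_train, cfg$ridge_param, cfg$tau)
  thresholds <- relay_thresholds(cfg$alpha, cfg$beta)
  summary_rows <- lapply(cfg$x_cen_values, function(x_cen) {
    tag <- gsub("\\.", "p", sprintf("xcen%g", x_cen))
    tryCatch(
      run_study_one(cfg, out_dir, x_cen, tag, realization, params, config,
                    thresholds, switching_time),
      error = function(e) data.frame(
        x_cen = x_cen, verdict = paste("error:", conditionMessage(e)),
        n_switching_rho = NA_integer_, continuation_csv = NA_character_))
  })
  out <- do.call(rbind, summary_rows)
  utils::write.csv(out, file.path(out_dir, "study_summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(study_sidecar(cfg),
                       file.path(out_dir, "study_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

run_study_one <- function(cfg, out_dir, x_cen, tag, realization, params,
                          config, thresholds, switching_time) {
    pair <- task_pair(x_cen)
    trained <- train_seeing_double(
      with_spectral_radius(realization, cfg$rho_start), params, pair, config)
    verdict <- multifunctionality_check(trained, pair, cfg$horizon, cfg$tol)
    jsonlite::write_json(
      study_sidecar(cfg, list(x_cen = x_cen, verdict = verdict$verdict,
                              diagnostics = verdict$diagnostics)),
      file.path(out_dir, paste0(tag, "_verdict.json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    tab <- continuation_sweep(realization, params, pair, cfg$rho_start,
                              cfg$rho_end, cfg$rho_step, config,
                              cfg$t_track, thresholds)
    csv <- file.path(out_dir, paste0(tag, "_continuation.csv"))
    utils::write.csv(continuation_long(tab), csv, row.names = FALSE)
    jsonlite::write_json(study_sidecar(cfg, list(x_cen = x_cen)),
                         paste0(csv, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    sw_rhos <- sort(unique(tab$rho[tab$label == "switching"]))
    if (length(sw_rhos) > 0) {
      rho_sw <- stats::median(sw_rhos)
      tr_sw <- train_seeing_double(
        with_spectral_radius(realization, rho_sw), params, pair, config)
      sw <- collect_switchings(tr_sw, tr_sw$end_state_A,
                               target_count = .Machine$integer.max,
                               thresholds = thresholds,
                               max_time = switching_time)
      utils::write.csv(sw$entries,
                       file.path(out_dir, paste0(tag, "_transitions.csv")),
                       row.names = FALSE)
      dur <- residence_durations(sw)
      for (st in c("A", "B")) {
        d <- dur[[paste0("durations_", st)]]
        if (length(d) >= 2 && length(unique(d)) >= 2) {
          h <- log_binned_density(d, n_bins = min(100, max(2, length(d))))
          utils::write.csv(
            data.frame(bin_left = h$bin_edges[-length(h$bin_edges)],
                       bin_right = h$bin_edges[-1],
                       density = h$density, counts = h$counts),
            file.path(out_dir,
                      paste0(tag, "_residence_", st, ".csv")),
            row.names = FALSE)
        }
      }
    }
    data.frame(x_cen = x_cen, verdict = verdict$verdict,
               n_switching_rho = length(sw_rhos),
               continuation_csv = csv)
}
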