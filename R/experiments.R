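## Configuration, experiment orchestration and log export.
##
## The defaults file encodes every model constant in one auditable place;
## any field can be overridden, and configs round-trip losslessly through
## YAML.

#' The default configuration
#'
#' All neuron, synapse, plasticity, reward, encoder, band, clock, motion
#' and experiment parameters. Units: mV / ms / nA / MOhm, cm and cm/s,
#' rad/s; `max_duration` in seconds.
#'
#' @return A nested named list (class `snnbot_config`).
#' @export
default_config <- function() {
  structure(list(
    neurons = list(if_tau = 1, if_R = 1, lif_tau = 5, lif_R = 1,
                   v_rest = 0, v_th = 30, t_ref = 2),
    synapse = list(tau_s = 10, gain_A = 0.5),
    plasticity = list(A_plus = 1, A_minus = -1, tau_plus = 10,
                      tau_minus = 10, tau_c = 10, tau_w = 1000,
                      w0 = 1, l = 3e-5, gamma0 = 1.2e-3),
    reward = list(tau_r = 2, C_r = 0.07),
    encoder = list(I0 = 0.225, C_i = 0.005, d_min = 15, d_max = 30,
                   gain = 10),
    bands = list(low_hz = 8, high_hz = 18),
    rate_window = 300,
    control_period = 100,
    dt = 0.1,
    motion = list(forward_speed = 4, turn_rate = 1.5),
    experiment = list(scenario = "single_left", trials = 3,
                      max_duration = 12, inter_trial_ms = 5000,
                      settle_ms = 1000, sensor_noise = 0, seed = 1)),
    class = "snnbot_config")
}

## recursive merge that rejects unknown keys (reported all at once)
merge_config <- function(base, override, path = character(0)) {
  if (is.null(override)) return(base)
  bad <- setdiff(names(override), names(base))
  if (length(bad))
    stop("unknown config key(s): ",
         paste(paste(c(path, ""), collapse = "$"), bad, sep = "",
               collapse = ", "))
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]], c(path, nm))
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Validate a configuration
#'
#' Checks every range constraint and reports all violations at once, each
#' with its key path.
#'
#' @param cfg Configuration list.
#' @return Invisibly `TRUE`, or an error enumerating the violations.
#' @export
validate_config <- function(cfg) {
  bad <- character(0)
  chk <- function(ok, path) if (!isTRUE(ok)) bad <<- c(bad, path)
  pos <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0
  num <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  chk(pos(cfg$neurons$if_tau), "neurons$if_tau must be > 0")
  chk(pos(cfg$neurons$lif_tau), "neurons$lif_tau must be > 0")
  chk(pos(cfg$neurons$if_R), "neurons$if_R must be > 0")
  chk(pos(cfg$neurons$lif_R), "neurons$lif_R must be > 0")
  chk(num(cfg$neurons$v_rest), "neurons$v_rest must be finite")
  chk(num(cfg$neurons$v_th) && cfg$neurons$v_th > cfg$neurons$v_rest,
      "neurons$v_th must exceed v_rest")
  chk(num(cfg$neurons$t_ref) && cfg$neurons$t_ref >= 0,
      "neurons$t_ref must be >= 0")
  chk(pos(cfg$synapse$tau_s), "synapse$tau_s must be > 0")
  chk(num(cfg$synapse$gain_A), "synapse$gain_A must be finite")
  p <- cfg$plasticity
  chk(num(p$A_plus) && p$A_plus >= 0, "plasticity$A_plus must be >= 0")
  chk(num(p$A_minus) && p$A_minus <= 0, "plasticity$A_minus must be <= 0")
  chk(pos(p$tau_plus), "plasticity$tau_plus must be > 0")
  chk(pos(p$tau_minus), "plasticity$tau_minus must be > 0")
  chk(pos(p$tau_c), "plasticity$tau_c must be > 0")
  chk(is.numeric(p$tau_w) && p$tau_w > 0, "plasticity$tau_w must be > 0")
  chk(num(p$w0) && p$w0 >= 0, "plasticity$w0 must be >= 0")
  chk(num(p$l) && p$l >= 0, "plasticity$l must be >= 0")
  chk(num(p$gamma0) && p$gamma0 >= 0, "plasticity$gamma0 must be >= 0")
  chk(pos(cfg$reward$tau_r), "reward$tau_r must be > 0")
  chk(num(cfg$reward$C_r) && cfg$reward$C_r >= 0, "reward$C_r must be >= 0")
  e <- cfg$encoder
  chk(num(e$I0), "encoder$I0 must be finite")
  chk(num(e$C_i), "encoder$C_i must be finite")
  chk(num(e$d_min) && num(e$d_max) && e$d_min >= 0 && e$d_min < e$d_max,
      "encoder$d_min/d_max must satisfy 0 <= d_min < d_max")
  chk(pos(e$gain), "encoder$gain must be > 0")
  if (num(e$I0) && num(e$C_i) && num(e$d_max))
    chk(e$I0 - e$C_i * e$d_max > 0, "encoder current must be positive at d_max")
  chk(num(cfg$bands$low_hz) && num(cfg$bands$high_hz) &&
        cfg$bands$low_hz < cfg$bands$high_hz,
      "bands$low_hz must be less than bands$high_hz")
  chk(pos(cfg$rate_window), "rate_window must be > 0")
  chk(pos(cfg$control_period), "control_period must be > 0")
  chk(pos(cfg$dt), "dt must be > 0")
  chk(pos(cfg$motion$forward_speed), "motion$forward_speed must be > 0")
  chk(pos(cfg$motion$turn_rate), "motion$turn_rate must be > 0")
  ex <- cfg$experiment
  chk(ex$scenario %in% c("single_left", "single_right", "slalom5"),
      "experiment$scenario must be a known scenario")
  chk(pos(ex$trials), "experiment$trials must be > 0")
  chk(pos(ex$max_duration), "experiment$max_duration must be > 0")
  chk(num(ex$sensor_noise) && ex$sensor_noise >= 0,
      "experiment$sensor_noise must be >= 0")
  if (length(bad))
    stop(paste(c("invalid configuration:", bad), collapse = "\n  - "))
  invisible(TRUE)
}

#' Load a configuration file
#'
#' Reads a YAML override file and merges it over [default_config()];
#' unknown keys and out-of-range values are rejected with their key paths.
#' An empty file yields the pure defaults.
#'
#' @param path Path to a YAML file.
#' @return A validated `snnbot_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  override <- yaml::read_yaml(path)
  cfg <- merge_config(default_config(), override)
  validate_config(cfg)
  cfg
}

#' Save a configuration file
#'
#' @param cfg An `snnbot_config`.
#' @param path Output YAML path.
#' @return Invisibly `path`.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

## shared setup for both experiments
build_experiment <- function(cfg) {
  spec <- calibrate_network(build_network(cfg))
  mp <- motion_params(cfg$motion$forward_speed, cfg$motion$turn_rate,
                      cfg$control_period)
  list(spec = spec, mp = mp)
}

## inter-trial relaxation: robot parked at range, weights decay to w0,
## learning rates persist
relax_state <- function(spec, state, duration_ms) {
  if (duration_ms <= 0) return(state)
  run_network(spec, state, spec$encoder$d_max, spec$encoder$d_max,
              duration_ms)$state
}

#' Single-obstacle learning experiment
#'
#' Runs `trials` consecutive closed-loop trials of a one-obstacle scenario
#' with the network state carried over: between trials the robot is
#' repositioned at the start pose and the network idles at maximum range so
#' the exercised weight relaxes to baseline while the learning rate keeps
#' its gains. The per-trial decision time is the interval from the first
#' reward release to the first non-straight command.
#'
#' @param cfg An `snnbot_config` (scenario must be `single_left` or
#'   `single_right`; `trials >= 2`).
#' @param state Optional starting network state (e.g. to continue training
#'   on the mirrored side).
#' @return An `experiment_summary`: per-trial decision times (s), collision
#'   flags, terminal causes, final learning rates, peak weights, the trial
#'   logs and the final network state.
#' @export
run_learning_experiment <- function(cfg, state = NULL) {
  stopifnot(cfg$experiment$scenario %in% c("single_left", "single_right"),
            cfg$experiment$trials >= 2)
  eb <- build_experiment(cfg)
  sc <- make_scenario(cfg$experiment$scenario)
  n <- cfg$experiment$trials
  logs <- vector("list", n)
  for (i in seq_len(n)) {
    logs[[i]] <- run_closed_loop(
      eb$spec, sc$world, sc$start, eb$mp,
      max_duration = cfg$experiment$max_duration,
      seed = cfg$experiment$seed + i - 1,
      state = state,
      settle_ms = cfg$experiment$settle_ms,
      sensor_noise = cfg$experiment$sensor_noise)
    state <- relax_state(eb$spec, logs[[i]]$state,
                         cfg$experiment$inter_trial_ms)
  }
  summarize_trials(logs, state, eb$spec)
}

#' Multi-obstacle course experiment
#'
#' Runs the slalom course (alternating obstacles, terminal double-width
#' wall). The network should be pre-trained: pass the final state of one
#' or two [run_learning_experiment()] calls, or set
#' `cfg$plasticity$gamma0` to a trained learning-rate value.
#'
#' @param cfg An `snnbot_config` with scenario `slalom5`.
#' @param state Optional pre-trained network state.
#' @return An `experiment_summary` with a single trial log; its `terminal`
#'   should be `"stop"` for a trained network.
#' @export
run_course_experiment <- function(cfg, state = NULL) {
  stopifnot(cfg$experiment$scenario == "slalom5")
  eb <- build_experiment(cfg)
  sc <- make_scenario("slalom5")
  log <- run_closed_loop(
    eb$spec, sc$world, sc$start, eb$mp,
    max_duration = cfg$experiment$max_duration,
    seed = cfg$experiment$seed,
    state = state,
    settle_ms = cfg$experiment$settle_ms,
    sensor_noise = cfg$experiment$sensor_noise)
  summarize_trials(list(log), log$state, eb$spec)
}

summarize_trials <- function(logs, state, spec) {
  structure(list(
    decision_times_s = vapply(logs, function(l) l$events$decision_time_s, 0),
    collisions = vapply(logs, function(l) l$terminal == "collision", TRUE),
    terminal = vapply(logs, function(l) l$terminal, ""),
    final_gamma = c(gamma12 = state$g12, gamma34 = state$g34),
    peak_w = c(w12 = max(vapply(logs, function(l) max(l$table$w12), 0)),
               w34 = max(vapply(logs, function(l) max(l$table$w34), 0))),
    logs = logs,
    final_state = state,
    spec = spec),
    class = "experiment_summary")
}

#' @export
print.experiment_summary <- function(x, ...) {
  cat(sprintf("<experiment_summary> %d trial(s)\n", length(x$logs)))
  cat("  decision times (s):",
      paste(sprintf("%.2f", x$decision_times_s), collapse = ", "), "\n")
  cat("  collisions:", sum(x$collisions),
      "| terminal:", paste(x$terminal, collapse = ", "), "\n")
  cat(sprintf("  final learning rates: gamma12 = %.4g, gamma34 = %.4g\n",
              x$final_gamma[["gamma12"]], x$final_gamma[["gamma34"]]))
  invisible(x)
}

#' Export a trial log to plain-text files
#'
#' Writes the per-control-period time series as CSV and the event/terminal
#' summary as YAML.
#'
#' @param log A `trial_log` from [run_closed_loop()].
#' @param directory Output directory (created if needed).
#' @param prefix File-name prefix (default `"trial"`).
#' @return Named character vector of the written paths.
#' @export
export_log <- function(log, directory, prefix = "trial") {
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  ts_path <- file.path(directory, paste0(prefix, "_timeseries.csv"))
  sm_path <- file.path(directory, paste0(prefix, "_summary.yaml"))
  utils::write.csv(log$table, ts_path, row.names = FALSE)
  yaml::write_yaml(list(terminal = log$terminal,
                        events = lapply(log$events, function(v)
                          if (is.na(v)) NULL else v)),
                   sm_path)
  c(timeseries = ts_path, summary = sm_path)
}

#' Save / load a trained-state snapshot
#'
#' Persists the slow variables that constitute the network's long-term
#' memory (the two learning rates) plus the weights, as structured text.
#'
#' @param state An `snn_state`.
#' @param path Output YAML path.
#' @return Invisibly `path` (`save_trained_state`) or an updated copy of a
#'   fresh state (`load_trained_state`).
#' @export
save_trained_state <- function(state, path) {
  yaml::write_yaml(list(gamma12 = state$g12, gamma34 = state$g34,
                        w12 = state$w12, w34 = state$w34), path,
                   precision = 15)
  invisible(path)
}

#' @rdname save_trained_state
#' @param spec Calibrated `snn_spec` used to initialise the state.
#' @export
load_trained_state <- function(spec, path) {
  snap <- yaml::read_yaml(path)
  st <- network_init(spec)
  st$g12 <- snap$gamma12; st$g34 <- snap$gamma34
  st$w12 <- snap$w12; st$w34 <- snap$w34
  st
}
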