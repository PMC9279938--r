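## Shared fixtures. Calibration and the learning experiments are
## deterministic but take seconds, so they are computed once per test run.

calibrated_spec <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- calibrate_network(build_network())
    cache
  }
})

## three single_left trials, then three single_right trials continuing from
## the same network state, then a relaxation interval: the "trained" robot
trained_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- default_config()
      left <- run_learning_experiment(cfg)
      cfgR <- cfg
      cfgR$experiment$scenario <- "single_right"
      right <- run_learning_experiment(cfgR, state = left$final_state)
      state <- run_network(right$spec, right$final_state, 30, 30, 5000)$state
      cache <<- list(left = left, right = right, state = state,
                     spec = right$spec)
    }
    cache
  }
})

## the multi-obstacle course run with the trained state (slow: ~2 min)
course_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- default_config()
      cfg$experiment$scenario <- "slalom5"
      cfg$experiment$max_duration <- 160
      cfg$motion <- list(forward_speed = 2, turn_rate = 0.5)
      cache <<- run_course_experiment(cfg, state = trained_run()$state)
    }
    cache
  }
})

## deterministic spike trains on the simulation grid
random_train <- function(n, t_max, dt = 0.1) {
  sort(sample(seq(dt, t_max, by = dt), n))
}

mirror_command <- function(cmd) {
  out <- cmd
  out[cmd == "left"] <- "right"
  out[cmd == "right"] <- "left"
  out
}
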