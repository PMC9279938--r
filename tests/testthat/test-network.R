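## Architecture, encoding, decoding, calibration and the clock-driven loop.

test_that("distance encoding follows the linear map with clipping", {
  ep <- encoder_params()
  raw <- encode_distance(encoder_params(gain = 1), 30, 15)
  expect_equal(unname(raw), c(0.075, 0.15))
  out <- encode_distance(ep, 50, 10)    # both clipped
  expect_equal(unname(out), 10 * c(0.075, 0.15))
  expect_error(encode_distance(ep, -1, 20), "non-negative")
  expect_error(encoder_params(I0 = 0.1, C_i = 0.005, d_max = 30), "positive")
})

test_that("the builder instantiates the exact architecture", {
  spec <- build_network()
  expect_length(spec$neurons, 10)
  expect_length(spec$plastic, 2)
  expect_setequal(names(spec$plastic), c("w12", "w34"))
  rn <- vapply(spec$plastic, function(p) p$reward_neuron, "")
  expect_setequal(unname(rn), c("R1", "R2"))
  ## mirror symmetry: swapping the two channels leaves parameters invariant
  expect_identical(spec$neurons$N1, spec$neurons$N3)
  expect_identical(spec$neurons$N2, spec$neurons$N4)
  expect_identical(spec$neurons$R1, spec$neurons$R2)
  expect_identical(spec$neurons$Left, spec$neurons$Right)
  ## channel-to-side assignment
  expect_identical(spec$plastic$w34$sensor_side, "left")
  expect_identical(spec$plastic$w12$sensor_side, "right")
  ## out polarities
  expect_identical(spec$static$N2_Out$polarity, "excitatory")
  expect_identical(spec$static$N4_Out$polarity, "inhibitory")
})

test_that("invalid configurations are rejected with the offending fields", {
  expect_error(build_network(list(synapse = list(tau_s = 0))), "tau_s")
  expect_error(build_network(list(bands = list(low_hz = 20))), "low_hz")
  expect_error(build_network(list(nonsense = 1)), "unknown config key")
})

test_that("sliding-window rate estimation counts spikes in (t-w, t]", {
  expect_equal(estimate_rate(seq(50, 1000, length.out = 12), 1000, 1000), 12)
  expect_equal(estimate_rate(numeric(0), 1000, 1000), 0)
  train <- seq(0, 5000, by = 40)    # 25 Hz
  rates <- vapply(seq(1000, 5000, by = 100), function(t)
    estimate_rate(train, t, 1000), 0)
  expect_true(all(abs(rates - 25) <= 1))
  expect_error(estimate_rate(1, 1, 0), "window")
})

test_that("band decoding maps rates to commands with inclusive boundaries", {
  expect_identical(decode_action(12, FALSE), "straight")
  expect_identical(decode_action(20, FALSE), "left")
  expect_identical(decode_action(5, FALSE), "right")
  expect_identical(decode_action(8, FALSE), "straight")
  expect_identical(decode_action(18, FALSE), "straight")
  expect_identical(decode_action(40, TRUE), "stop")
  expect_identical(decode_action(0, TRUE), "stop")
})

test_that("calibration hits every operating point in its report", {
  spec <- calibrated_spec()
  rep <- spec$calib$report
  expect_equal(rep$encoder_rate_dmax, 25, tolerance = 0.1)
  expect_equal(rep$encoder_rate_dmin, 50, tolerance = 0.1)
  expect_equal(rep$pacemaker_rate, 25, tolerance = 0.04)
  expect_gte(rep$baseline_out_rate, spec$bands[["low_hz"]])
  expect_lte(rep$baseline_out_rate, spec$bands[["high_hz"]])
  expect_identical(rep$baseline_releases, 0L)
  expect_identical(rep$gate_baseline_releases_5s, 0L)
  expect_identical(rep$gate_doubled_baseline_releases_5s, 0L)
  expect_gte(rep$gate_releases_200ms, 1L)
  expect_identical(rep$stop_unilateral_5s, 0L)
  expect_gte(rep$stop_bilateral_500ms, 1L)
})

test_that("dopamine gate releases need sensor drive and relay spikes together", {
  spec <- calibrated_spec()
  params <- list(neuron = spec$neurons$R2,
                 pulse_syn = spec$synapse$excitatory,
                 pulse_weight = spec$calib$gate_pulse_weight)
  fresh <- function() list(neuron = neuron_state(spec$neurons$R2),
                           pulse = synapse_state(spec$synapse$excitatory),
                           reward = reward_state(spec$reward$tau_r,
                                                 spec$reward$C_r))
  run_gate <- function(drive, relay_period_ms, duration) {
    ch <- fresh()
    releases <- 0L
    for (k in seq_len(round(duration / 0.1))) {
      relay <- relay_period_ms > 0 && (k %% round(relay_period_ms / 0.1)) == 0
      up <- dopamine_gate_step(ch, params, drive, relay, 0.1, k * 0.1)
      ch <- up$channel
      if (up$released) releases <- releases + 1L
    }
    releases
  }
  drive_near <- spec$calib$gate_drive_gain * 0.15    # d_min equivalent
  drive_far <- spec$calib$gate_drive_gain * 0.075    # d_max equivalent
  expect_identical(run_gate(0, 0, 500), 0L)                 # nothing
  expect_identical(run_gate(drive_near, 0, 500), 0L)        # sensor alone
  expect_identical(run_gate(0, 40, 500), 0L)                # relay alone
  expect_gte(run_gate(drive_near, 40, 200), 1L)             # conjunction
  expect_identical(run_gate(drive_far, 40, 1000), 0L)       # far + relay
})

test_that("reward tracks the gate releases inside the full network", {
  spec <- calibrated_spec()
  out <- run_network(spec, network_init(spec), 15, 30, 500, record = TRUE)
  rec <- out$record
  rel_steps <- which(rec[, "rel2"] == 1)
  expect_gte(length(rel_steps), 1)
  ## r2 jumps by C_r at each release step
  prev <- c(0, rec[-nrow(rec), "r2"])
  expect_true(all(abs(rec[rel_steps, "r2"] -
                        (prev[rel_steps] * exp(-0.1 / 2) + 0.07)) < 1e-12))
  expect_identical(sum(rec[, "rel1"]), 0)   # far channel silent
})

test_that("the fast network loop reproduces the single-step operations exactly", {
  spec <- calibrated_spec()
  cal <- spec$calib
  dt <- spec$dt
  n_steps <- 3000L
  d_left <- 15; d_right <- 27

  loop <- run_network(spec, network_init(spec), d_left, d_right,
                      n_steps * dt, record = TRUE)$record

  ## reference driver composed from the exported operations, following the
  ## documented update order (neurons -> synapses -> plasticity)
  ep <- spec$encoder
  Ienc <- encode_distance(ep, d_left, d_right)
  drv_R2 <- cal$gate_drive_gain * (ep$I0 - ep$C_i * max(min(d_left, ep$d_max), ep$d_min))
  drv_R1 <- cal$gate_drive_gain * (ep$I0 - ep$C_i * max(min(d_right, ep$d_max), ep$d_min))
  pl <- spec$plasticity
  exc <- spec$synapse$excitatory

  nst <- lapply(spec$neurons, neuron_state)
  syn <- list(sy12 = synapse_state(exc), sy34 = synapse_state(exc),
              s2o = synapse_state(exc), s4o = synapse_state(exc),
              s2r1 = synapse_state(exc), s4r2 = synapse_state(exc),
              sLs = synapse_state(exc), sRs = synapse_state(exc))
  ps12 <- plastic_synapse_state(pl); ps34 <- plastic_synapse_state(pl)
  rw1 <- reward_state(spec$reward$tau_r, spec$reward$C_r)
  rw2 <- reward_state(spec$reward$tau_r, spec$reward$C_r)

  ok <- TRUE
  for (k in seq_len(n_steps)) {
    t <- k * dt
    up <- if_step(spec$neurons$Left, nst$Left, Ienc[["I_left"]], t, dt)
    nst$Left <- up$state; spkL <- up$spiked
    up <- if_step(spec$neurons$Right, nst$Right, Ienc[["I_right"]], t, dt)
    nst$Right <- up$state; spkR <- up$spiked
    up <- lif_step(spec$neurons$N1, nst$N1, cal$pacemaker_bias, t, dt)
    nst$N1 <- up$state; spkN1 <- up$spiked
    up <- lif_step(spec$neurons$N3, nst$N3, cal$pacemaker_bias, t, dt)
    nst$N3 <- up$state; spkN3 <- up$spiked
    up <- lif_step(spec$neurons$N2, nst$N2,
                   cal$relay_drive_gain * syn$sy12$I_syn, t, dt)
    nst$N2 <- up$state; spkN2 <- up$spiked
    up <- lif_step(spec$neurons$N4, nst$N4,
                   cal$relay_drive_gain * syn$sy34$I_syn, t, dt)
    nst$N4 <- up$state; spkN4 <- up$spiked
    up <- lif_step(spec$neurons$Out, nst$Out,
                   cal$out_bias + (syn$s2o$I_syn - syn$s4o$I_syn), t, dt)
    nst$Out <- up$state; spkOut <- up$spiked
    up <- lif_step(spec$neurons$Stop, nst$Stop,
                   syn$sLs$I_syn + syn$sRs$I_syn, t, dt)
    nst$Stop <- up$state
    up <- lif_step(spec$neurons$R1, nst$R1, drv_R1 + syn$s2r1$I_syn, t, dt)
    nst$R1 <- up$state; rel1 <- up$spiked
    up <- lif_step(spec$neurons$R2, nst$R2, drv_R2 + syn$s4r2$I_syn, t, dt)
    nst$R2 <- up$state; rel2 <- up$spiked

    syn$sy12 <- synapse_step(exc, syn$sy12, spkN1, ps12$w, dt)
    syn$sy34 <- synapse_step(exc, syn$sy34, spkN3, ps34$w, dt)
    syn$s2o <- synapse_step(exc, syn$s2o, spkN2, cal$W_out_exc, dt)
    syn$s4o <- synapse_step(exc, syn$s4o, spkN4, cal$W_out_inh, dt)
    syn$s2r1 <- synapse_step(exc, syn$s2r1, spkN2, cal$gate_pulse_weight, dt)
    syn$s4r2 <- synapse_step(exc, syn$s4r2, spkN4, cal$gate_pulse_weight, dt)
    syn$sLs <- synapse_step(exc, syn$sLs, spkL, cal$W_stop, dt)
    syn$sRs <- synapse_step(exc, syn$sRs, spkR, cal$W_stop, dt)

    step_channel <- function(ps, rw, pre, post, released) {
      ps <- update_traces(pl, ps, FALSE, FALSE, dt)   # decay only
      inc <- stdp_increment(pl, ps, pre, post)
      if (pre) ps$x <- ps$x + 1
      if (post) ps$y <- ps$y + 1
      ps <- update_eligibility(pl, ps, inc, dt)
      rw <- update_reward(rw, as.integer(released), dt)
      ps <- improved_rule_step(pl, ps, rw$r, dt)
      list(ps = ps, rw = rw)
    }
    ch <- step_channel(ps12, rw1, spkN1, spkN2, rel1)
    ps12 <- ch$ps; rw1 <- ch$rw
    ch <- step_channel(ps34, rw2, spkN3, spkN4, rel2)
    ps34 <- ch$ps; rw2 <- ch$rw

    ok <- ok &&
      identical(unname(loop[k, "vOut"]), nst$Out$v) &&
      identical(unname(loop[k, "vN2"]), nst$N2$v) &&
      identical(unname(loop[k, "vN4"]), nst$N4$v) &&
      identical(unname(loop[k, "vR2"]), nst$R2$v) &&
      identical(unname(loop[k, "w12"]), ps12$w) &&
      identical(unname(loop[k, "w34"]), ps34$w) &&
      identical(unname(loop[k, "g34"]), ps34$gamma) &&
      identical(unname(loop[k, "c34"]), ps34$c) &&
      identical(unname(loop[k, "r2"]), rw2$r)
    if (!ok) break
  }
  expect_true(ok)
})

test_that("single steps compose to the same run as one long call", {
  spec <- calibrated_spec()
  a <- run_network(spec, network_init(spec), 20, 30, 50)$state
  b <- network_init(spec)
  for (k in 1:500) b <- network_step(spec, b, 20, 30)$state
  expect_identical(a, b)
})

test_that("baseline input leaves weights at w0 and produces no reward", {
  spec <- calibrated_spec()
  out <- run_network(spec, network_init(spec), 30, 30, 3000)
  expect_identical(out$counts$rel1 + out$counts$rel2, 0L)
  expect_identical(out$state$w12, 1)
  expect_identical(out$state$w34, 1)
})

test_that("sustained proximity drives the correct weight and decision side", {
  spec <- calibrated_spec()
  st <- run_network(spec, network_init(spec), 30, 30, 1000)$state
  left <- run_network(spec, st, 15, 30, 4000)
  expect_gt(left$state$w34, 1.005)
  expect_equal(left$state$w12, 1)
  expect_gt(left$state$g34, spec$plasticity$gamma0)
  ## Out is suppressed below the straight band -> turn right
  tail_rate <- run_network(spec, left$state, 15, 30, 1000)$counts$out
  expect_lt(tail_rate, spec$bands[["low_hz"]])
  ## mirrored input elevates Out above the band -> turn left
  st2 <- run_network(spec, network_init(spec), 30, 30, 1000)$state
  right <- run_network(spec, st2, 30, 15, 4000)
  expect_gt(right$state$w12, 1.005)
  tail2 <- run_network(spec, right$state, 30, 15, 1000)$counts$out
  expect_gt(tail2, spec$bands[["high_hz"]])
})

test_that("learning-rate memory survives weight relaxation", {
  spec <- calibrated_spec()
  st <- run_network(spec, network_init(spec), 30, 30, 1000)$state
  st <- run_network(spec, st, 15, 30, 4000)$state
  g_after <- st$g34
  st <- run_network(spec, st, 30, 30, 6000)$state
  expect_lt(abs(st$w34 - 1), 0.005)          # weight forgot
  expect_gte(st$g34, g_after)                # learning rate remembered
  expect_equal(st$g34, g_after, tolerance = 1e-6)
  expect_gt(g_after, spec$plasticity$gamma0)
})
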