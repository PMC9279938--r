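## The ten-neuron obstacle-avoidance controller.
##
## Architecture (all names fixed): two perfect-integrator encoders (Left,
## Right) translate ultrasonic distances into spike trains; two pacemakers
## (N1, N3) fire at 25 Hz under a calibrated constant bias; two relays
## (N2, N4) are driven by the pacemakers through the only two plastic
## synapses (w12: N1->N2, w34: N3->N4); a decision neuron (Out) receives
## N2 excitation and N4 inhibition plus a calibrated bias that holds its
## baseline rate at ~12 Hz; a brake neuron (Stop) receives both encoders
## and fires only under bilateral proximity; two dopaminergic release
## units (R1, R2) are driven by the opposite-side sensor current plus a
## pulse from their paired relay, and each release feeds the decaying
## reward variable of its own plastic synapse (R1 -> w12, R2 -> w34).
##
## Readout design: the functional contract is that a LEFT obstacle drives
## the Out rate BELOW the straight band (turn right) and a RIGHT obstacle
## drives it ABOVE (turn left). At baseline both relays fire one spike per
## pacemaker period at identical times, so their equally-weighted
## excitatory (N2) and inhibitory (N4) pulses cancel exactly at Out, which
## then fires at exactly the bias-driven 12 Hz operating point. The relay
## drive gain is calibrated so that a small increase of a plastic weight
## tips its relay into a two-spikes-per-period regime; the un-cancelled
## second pulse then drives Out with that synapse's sign: extra N4 spikes
## (left obstacle, w34 up) silence Out, extra N2 spikes (right obstacle,
## w12 up) lock it to the burst rate. The channel-to-side assignment is
## Left sensor -> R2 -> w34 and Right sensor -> R1 -> w12.

#' Distance-encoder parameters
#'
#' Linear mapping from a sensed distance to an injected current,
#' `I = gain * (I0 - C_i * d)` with `d` clipped to `[d_min, d_max]`.
#' The table constants give 0.075 nA at `d_max` and 0.15 nA at `d_min`;
#' the fixed `gain = 10` (equivalently a 10 MOhm encoder resistance)
#' makes the encoder integrator fire at the stated 25 Hz / 50 Hz
#' operating points, which the raw constants alone do not reach.
#'
#' @param I0 Base current, nA (default 0.225).
#' @param C_i Distance-to-current slope, nA/cm (default 0.005).
#' @param d_min,d_max Sensor clip range, cm (defaults 15 and 30).
#' @param gain Dimensionless multiplier applied to the encoder current.
#' @return An object of class `encoder_params`.
#' @export
encoder_params <- function(I0 = 0.225, C_i = 0.005, d_min = 15, d_max = 30,
                           gain = 10) {
  stopifnot(is.finite(I0), is.finite(C_i), is.finite(d_min), is.finite(d_max),
            is.finite(gain), gain > 0, d_min < d_max, d_min >= 0)
  if (I0 - C_i * d_max <= 0)
    stop("encoder current must stay positive at d_max (I0 - C_i*d_max > 0)")
  structure(list(I0 = I0, C_i = C_i, d_min = d_min, d_max = d_max,
                 gain = gain),
            class = "encoder_params")
}

## current before the encoder gain (also used, with its own gain, by the
## dopaminergic release units)
raw_distance_current <- function(ep, d) {
  d <- pmin(pmax(d, ep$d_min), ep$d_max)
  ep$I0 - ep$C_i * d
}

#' Encode a pair of sensor distances into injected currents
#'
#' @param ep [encoder_params()].
#' @param d_left,d_right Distances, cm; values outside the clip range are
#'   clipped before the linear mapping. Negative distances are rejected.
#' @return Named numeric vector `c(I_left =, I_right =)` in nA (gain applied).
#' @examples
#' encode_distance(encoder_params(), 30, 15)
#' @export
encode_distance <- function(ep, d_left, d_right) {
  stopifnot(is.finite(d_left), is.finite(d_right))
  if (d_left < 0 || d_right < 0) stop("distances must be non-negative")
  c(I_left = ep$gain * raw_distance_current(ep, d_left),
    I_right = ep$gain * raw_distance_current(ep, d_right))
}

#' Build the ten-neuron controller specification
#'
#' Assembles neuron parameter sets, wiring, plasticity and reward constants
#' into an uncalibrated network spec. Pass the result to
#' [calibrate_network()] before simulating. `config` may override any
#' parameter group; see [default_config()] for the full schema.
#'
#' @param config Optional configuration list (as from [default_config()] or
#'   [load_config()]); `NULL` uses the defaults.
#' @return An object of class `snn_spec`.
#' @examples
#' spec <- build_network()
#' length(spec$neurons)      # 10
#' names(spec$plastic)       # "w12" "w34"
#' @export
build_network <- function(config = NULL) {
  cfg <- if (is.null(config)) default_config() else
    merge_config(default_config(), config)
  validate_config(cfg)
  nc <- cfg$neurons
  enc <- do.call(encoder_params, cfg$encoder)
  ifp <- function() neuron_params("integrator", tau = nc$if_tau, R = nc$if_R,
                                  v_rest = nc$v_rest, v_th = nc$v_th)
  lifp <- function(bias = 0)
    neuron_params("leaky", tau = nc$lif_tau, R = nc$lif_R,
                  v_rest = nc$v_rest, v_th = nc$v_th, t_ref = nc$t_ref,
                  bias_current = bias)
  neurons <- list(Left = ifp(), Right = ifp(),
                  N1 = lifp(), N2 = lifp(), N3 = lifp(), N4 = lifp(),
                  R1 = lifp(), R2 = lifp(), Out = lifp(), Stop = lifp())
  syn_ex <- synapse_params(tau_s = cfg$synapse$tau_s,
                           gain_A = cfg$synapse$gain_A, "excitatory")
  syn_in <- synapse_params(tau_s = cfg$synapse$tau_s,
                           gain_A = cfg$synapse$gain_A, "inhibitory")
  plas <- do.call(plasticity_params, cfg$plasticity)
  spec <- structure(list(
    neurons = neurons,
    encoder = enc,
    synapse = list(excitatory = syn_ex, inhibitory = syn_in),
    plasticity = plas,
    ## the two plastic synapses and their reward channels
    plastic = list(
      w12 = list(pre = "N1", post = "N2", reward_neuron = "R1",
                 sensor_side = "right"),
      w34 = list(pre = "N3", post = "N4", reward_neuron = "R2",
                 sensor_side = "left")),
    reward = list(tau_r = cfg$reward$tau_r, C_r = cfg$reward$C_r),
    ## static wiring: target <- source, polarity; weights set by calibration
    static = list(
      N2_Out  = list(pre = "N2",   post = "Out",  polarity = "excitatory"),
      N4_Out  = list(pre = "N4",   post = "Out",  polarity = "inhibitory"),
      N2_R1   = list(pre = "N2",   post = "R1",   polarity = "excitatory"),
      N4_R2   = list(pre = "N4",   post = "R2",   polarity = "excitatory"),
      Left_Stop  = list(pre = "Left",  post = "Stop", polarity = "excitatory"),
      Right_Stop = list(pre = "Right", post = "Stop", polarity = "excitatory")),
    bands = c(low_hz = cfg$bands$low_hz, high_hz = cfg$bands$high_hz),
    rate_window = cfg$rate_window,
    control_period = cfg$control_period,
    dt = cfg$dt,
    calib = NULL),
    class = "snn_spec")
  validate_network(spec)
  spec
}

#' Validate a network spec
#'
#' Checks the structural invariants of the architecture: exactly ten
#' neuron units, exactly two plastic synapses, exactly two reward channels,
#' mirror symmetry of the two channels, and positive band/window constants.
#'
#' @param spec An `snn_spec` object.
#' @return Invisibly `TRUE`; otherwise an error listing every violation.
#' @export
validate_network <- function(spec) {
  problems <- character(0)
  need <- c("Left", "Right", "N1", "N2", "N3", "N4", "R1", "R2", "Out", "Stop")
  if (!identical(sort(names(spec$neurons)), sort(need)) ||
      length(spec$neurons) != 10)
    problems <- c(problems, "network must have exactly the 10 named neuron units")
  if (length(spec$plastic) != 2 ||
      !identical(sort(names(spec$plastic)), c("w12", "w34")))
    problems <- c(problems, "network must have exactly 2 plastic synapses (w12, w34)")
  rn <- vapply(spec$plastic, function(p) p$reward_neuron, "")
  if (length(unique(rn)) != 2 || !all(sort(unname(rn)) == c("R1", "R2")))
    problems <- c(problems, "network must have exactly 2 reward channels (R1, R2)")
  ## mirror symmetry of the channel parameters
  mirror_pairs <- list(c("Left", "Right"), c("N1", "N3"), c("N2", "N4"),
                       c("R1", "R2"))
  for (pr in mirror_pairs)
    if (!identical(unclass(spec$neurons[[pr[1]]]),
                   unclass(spec$neurons[[pr[2]]])))
      problems <- c(problems,
                    sprintf("mirrored units %s/%s have different parameters",
                            pr[1], pr[2]))
  b <- spec$bands
  if (!(is.finite(b[["low_hz"]]) && is.finite(b[["high_hz"]]) &&
        b[["low_hz"]] < b[["high_hz"]]))
    problems <- c(problems, "decision bands must satisfy low_hz < high_hz")
  if (!(spec$rate_window > 0 && spec$control_period > 0 && spec$dt > 0))
    problems <- c(problems, "rate_window, control_period and dt must be positive")
  if (length(problems))
    stop(paste(c("invalid network spec:", problems), collapse = "\n  - "))
  invisible(TRUE)
}

#' @export
print.snn_spec <- function(x, ...) {
  cat("<snn_spec> 10-neuron obstacle-avoidance controller\n")
  cat("  plastic synapses: w12 (N1->N2, reward R1), w34 (N3->N4, reward R2)\n")
  cat(sprintf("  bands: straight [%g, %g] Hz; dt = %g ms; control period = %g ms\n",
              x$bands[["low_hz"]], x$bands[["high_hz"]], x$dt, x$control_period))
  cat(if (is.null(x$calib)) "  (uncalibrated)\n" else
    sprintf("  calibrated: pacemaker bias %.6f nA, Out bias %.8f nA, W_stop %.2f, gate pulse %.2f\n",
            x$calib$pacemaker_bias, x$calib$out_bias, x$calib$W_stop,
            x$calib$gate_pulse_weight))
  invisible(x)
}

#' Sliding-window firing-rate estimate
#'
#' Counts spikes in the half-open interval `(t_now - window, t_now]` and
#' divides by the window length.
#'
#' @param spike_times Numeric vector of spike times, ms.
#' @param t_now Current time, ms.
#' @param window Window length, ms (> 0).
#' @return Rate in Hz.
#' @examples
#' estimate_rate(seq(0, 1000, by = 40), t_now = 1000, window = 1000)
#' @export
estimate_rate <- function(spike_times, t_now, window) {
  stopifnot(window > 0)
  n <- sum(spike_times > t_now - window & spike_times <= t_now)
  1000 * n / window
}

#' Decode the Out/Stop activity into a motion command
#'
#' Stop dominates; otherwise the Out rate is mapped through the decision
#' bands, with both boundaries inclusive for "straight".
#'
#' @param out_rate Out-neuron firing rate, Hz (>= 0).
#' @param stop_active Logical: is the brake neuron active?
#' @param bands Named vector `c(low_hz =, high_hz =)` (defaults 8 and 18).
#' @return One of `"stop"`, `"left"`, `"right"`, `"straight"`.
#' @examples
#' decode_action(12, FALSE)   # straight
#' decode_action(20, FALSE)   # left
#' decode_action(5, FALSE)    # right
#' decode_action(12, TRUE)    # stop
#' @export
decode_action <- function(out_rate, stop_active,
                          bands = c(low_hz = 8, high_hz = 18)) {
  stopifnot(out_rate >= 0)
  if (isTRUE(stop_active)) return("stop")
  if (out_rate > bands[["high_hz"]]) return("left")
  if (out_rate < bands[["low_hz"]]) return("right")
  "straight"
}

#' One step of a dopaminergic release unit
#'
#' The release unit is a leaky neuron integrating the (gain-scaled) sensor
#' current plus a synaptic pulse fed by its paired relay's spikes. A
#' threshold crossing emits one release event into the channel's reward
#' variable instead of a spike; the membrane resets and the usual
#' refractory period applies.
#'
#' @param channel Channel state: `list(neuron = <neuron_state>, pulse =
#'   <synapse_state>, reward = <reward_state>)`.
#' @param params List with `neuron` ([neuron_params()], leaky), `pulse_syn`
#'   ([synapse_params()]) and `pulse_weight`.
#' @param sensor_drive Direct current from the sensor pathway, nA.
#' @param paired_relay_spiked Logical: did the paired relay fire this step?
#' @param dt Step size, ms.
#' @param t Current time, ms.
#' @return `list(channel = <new state>, released = <logical>)`.
#' @export
dopamine_gate_step <- function(channel, params, sensor_drive,
                               paired_relay_spiked, dt, t = NA_real_) {
  I <- sensor_drive + synapse_current(params$pulse_syn, channel$pulse)
  up <- lif_step(params$neuron, channel$neuron, I, t, dt)
  channel$neuron <- up$state
  released <- up$spiked
  channel$pulse <- synapse_step(params$pulse_syn, channel$pulse,
                                paired_relay_spiked, params$pulse_weight, dt)
  channel$reward <- update_reward(channel$reward, as.integer(released), dt, t)
  list(channel = channel, released = released)
}

## ---------------------------------------------------------------------------
## runtime state and the clock-driven inner loop

#' Fresh runtime state for a network
#'
#' All membrane potentials at rest, synaptic currents and traces at zero,
#' weights at `w0`, learning rates at `gamma0`, reward variables at zero.
#'
#' @param spec A (preferably calibrated) `snn_spec`.
#' @return Named list of state scalars (class `snn_state`).
#' @export
network_init <- function(spec) {
  vr <- spec$neurons$N1$v_rest
  p <- spec$plasticity
  structure(list(
    vL = spec$neurons$Left$v_rest, vR = spec$neurons$Right$v_rest,
    vN1 = vr, refN1 = 0, vN2 = vr, refN2 = 0,
    vN3 = vr, refN3 = 0, vN4 = vr, refN4 = 0,
    vOut = vr, refOut = 0, vStop = vr, refStop = 0,
    vR1 = vr, refR1 = 0, vR2 = vr, refR2 = 0,
    sy12 = 0, sy34 = 0, s2o = 0, s4o = 0, s2r1 = 0, s4r2 = 0,
    sLs = 0, sRs = 0,
    x12 = 0, y12 = 0, c12 = 0, w12 = p$w0, g12 = p$gamma0,
    x34 = 0, y34 = 0, c34 = 0, w34 = p$w0, g34 = p$gamma0,
    r1 = 0, r2 = 0, t = 0),
    class = "snn_state")
}

## One contiguous run at fixed sensor distances. This is the hot loop: all
## state lives in local scalars and the arithmetic reproduces, operation
## for operation, the exported single-step functions (guarded by a test
## that composes those functions and demands bitwise-equal trajectories).
run_chunk <- function(spec, st, d_left, d_right, n_steps,
                      plastic = TRUE, record = FALSE) {
  cal <- spec$calib
  if (is.null(cal)) stop("network must be calibrated before simulation")
  dt <- spec$dt
  ep <- spec$encoder
  Ienc <- encode_distance(ep, d_left, d_right)
  I_left <- Ienc[["I_left"]]; I_right <- Ienc[["I_right"]]
  drive_R2 <- cal$gate_drive_gain * raw_distance_current(ep, d_left)
  drive_R1 <- cal$gate_drive_gain * raw_distance_current(ep, d_right)

  ## constants
  npL <- spec$neurons$Left; npN <- spec$neurons$N1
  tau_e <- npL$tau; R_e <- npL$R; vr_e <- npL$v_rest; vth_e <- npL$v_th
  tau_m <- npN$tau; R_m <- npN$R; vr <- npN$v_rest; vth <- npN$v_th
  tref <- npN$t_ref
  dm <- exp(-dt / tau_m); dtR <- dt * R_m
  ds <- exp(-dt / spec$synapse$excitatory$tau_s)
  A <- spec$synapse$excitatory$gain_A
  pl <- spec$plasticity
  dxp <- exp(-dt / pl$tau_plus); dxm <- exp(-dt / pl$tau_minus)
  dc <- exp(-dt / pl$tau_c)
  A_plus <- pl$A_plus; A_minus <- pl$A_minus
  w0 <- pl$w0; tau_w <- pl$tau_w; dtl <- dt * pl$l
  dr <- exp(-dt / spec$reward$tau_r); C_r <- spec$reward$C_r
  bias_pm <- cal$pacemaker_bias; bias_out <- cal$out_bias
  W_oe <- cal$W_out_exc; W_oi <- cal$W_out_inh
  W_stop <- cal$W_stop; W_p <- cal$gate_pulse_weight
  G_rel <- cal$relay_drive_gain

  ## unpack state
  vL <- st$vL; vR <- st$vR
  vN1 <- st$vN1; refN1 <- st$refN1; vN2 <- st$vN2; refN2 <- st$refN2
  vN3 <- st$vN3; refN3 <- st$refN3; vN4 <- st$vN4; refN4 <- st$refN4
  vOut <- st$vOut; refOut <- st$refOut; vStop <- st$vStop; refStop <- st$refStop
  vR1 <- st$vR1; refR1 <- st$refR1; vR2 <- st$vR2; refR2 <- st$refR2
  sy12 <- st$sy12; sy34 <- st$sy34; s2o <- st$s2o; s4o <- st$s4o
  s2r1 <- st$s2r1; s4r2 <- st$s4r2; sLs <- st$sLs; sRs <- st$sRs
  x12 <- st$x12; y12 <- st$y12; c12 <- st$c12; w12 <- st$w12; g12 <- st$g12
  x34 <- st$x34; y34 <- st$y34; c34 <- st$c34; w34 <- st$w34; g34 <- st$g34
  r1 <- st$r1; r2 <- st$r2; t <- st$t

  cOut <- 0L; cStop <- 0L; cN2 <- 0L; cN4 <- 0L; cL <- 0L; cRt <- 0L
  cRel1 <- 0L; cRel2 <- 0L
  first_rel_t <- NA_real_
  rec <- if (record)
    matrix(NA_real_, n_steps, 22,
           dimnames = list(NULL, c(
             "t", "vL", "vR", "vN1", "vN2", "vN3", "vN4", "vOut", "vStop",
             "vR1", "vR2", "w12", "w34", "g12", "g34", "c12", "c34",
             "r1", "r2", "spkOut", "rel1", "rel2"))) else NULL

  for (k in seq_len(n_steps)) {
    t <- t + dt

    ## --- neuron updates (synaptic currents are from the previous step) ---
    vL <- vL + (dt * (vr_e + R_e * I_left)) / tau_e
    spkL <- vL >= vth_e
    if (spkL) { vL <- vr_e; cL <- cL + 1L }
    vR <- vR + (dt * (vr_e + R_e * I_right)) / tau_e
    spkR <- vR >= vth_e
    if (spkR) { vR <- vr_e; cRt <- cRt + 1L }

    if (refN1 > 0) { refN1 <- max(0, refN1 - dt); vN1 <- vr; spkN1 <- FALSE
    } else {
      vN1 <- vr + (vN1 - vr) * dm + (dtR * bias_pm) / tau_m
      spkN1 <- vN1 >= vth
      if (spkN1) { vN1 <- vr; refN1 <- tref }
    }
    if (refN3 > 0) { refN3 <- max(0, refN3 - dt); vN3 <- vr; spkN3 <- FALSE
    } else {
      vN3 <- vr + (vN3 - vr) * dm + (dtR * bias_pm) / tau_m
      spkN3 <- vN3 >= vth
      if (spkN3) { vN3 <- vr; refN3 <- tref }
    }

    if (refN2 > 0) { refN2 <- max(0, refN2 - dt); vN2 <- vr; spkN2 <- FALSE
    } else {
      vN2 <- vr + (vN2 - vr) * dm + (dtR * (G_rel * sy12)) / tau_m
      spkN2 <- vN2 >= vth
      if (spkN2) { vN2 <- vr; refN2 <- tref }
    }
    if (spkN2) cN2 <- cN2 + 1L
    if (refN4 > 0) { refN4 <- max(0, refN4 - dt); vN4 <- vr; spkN4 <- FALSE
    } else {
      vN4 <- vr + (vN4 - vr) * dm + (dtR * (G_rel * sy34)) / tau_m
      spkN4 <- vN4 >= vth
      if (spkN4) { vN4 <- vr; refN4 <- tref }
    }
    if (spkN4) cN4 <- cN4 + 1L

    if (refOut > 0) { refOut <- max(0, refOut - dt); vOut <- vr; spkOut <- FALSE
    } else {
      vOut <- vr + (vOut - vr) * dm + (dtR * (bias_out + (s2o - s4o))) / tau_m
      spkOut <- vOut >= vth
      if (spkOut) { vOut <- vr; refOut <- tref }
    }
    if (spkOut) cOut <- cOut + 1L

    if (refStop > 0) { refStop <- max(0, refStop - dt); vStop <- vr
      spkStop <- FALSE
    } else {
      vStop <- vr + (vStop - vr) * dm + (dtR * (sLs + sRs)) / tau_m
      spkStop <- vStop >= vth
      if (spkStop) { vStop <- vr; refStop <- tref }
    }
    if (spkStop) cStop <- cStop + 1L

    if (refR1 > 0) { refR1 <- max(0, refR1 - dt); vR1 <- vr; rel1 <- FALSE
    } else {
      vR1 <- vr + (vR1 - vr) * dm + (dtR * (drive_R1 + s2r1)) / tau_m
      rel1 <- vR1 >= vth
      if (rel1) { vR1 <- vr; refR1 <- tref }
    }
    if (rel1) { cRel1 <- cRel1 + 1L
      if (is.na(first_rel_t)) first_rel_t <- t }
    if (refR2 > 0) { refR2 <- max(0, refR2 - dt); vR2 <- vr; rel2 <- FALSE
    } else {
      vR2 <- vr + (vR2 - vr) * dm + (dtR * (drive_R2 + s4r2)) / tau_m
      rel2 <- vR2 >= vth
      if (rel2) { vR2 <- vr; refR2 <- tref }
    }
    if (rel2) { cRel2 <- cRel2 + 1L
      if (is.na(first_rel_t)) first_rel_t <- t }

    ## --- synapse updates (this step's spikes land with one-step delay) ---
    sy12 <- sy12 * ds; if (spkN1) sy12 <- sy12 + w12 * A
    sy34 <- sy34 * ds; if (spkN3) sy34 <- sy34 + w34 * A
    s2o <- s2o * ds; if (spkN2) s2o <- s2o + W_oe * A
    s4o <- s4o * ds; if (spkN4) s4o <- s4o + W_oi * A
    s2r1 <- s2r1 * ds; if (spkN2) s2r1 <- s2r1 + W_p * A
    s4r2 <- s4r2 * ds; if (spkN4) s4r2 <- s4r2 + W_p * A
    sLs <- sLs * ds; if (spkL) sLs <- sLs + W_stop * A
    sRs <- sRs * ds; if (spkR) sRs <- sRs + W_stop * A

    ## --- plasticity: traces, eligibility, reward, improved rule ---
    if (plastic) {
      x12 <- x12 * dxp; y12 <- y12 * dxm
      inc12 <- 0
      if (spkN1) inc12 <- inc12 + A_minus * y12
      if (spkN2) inc12 <- inc12 + A_plus * x12
      if (spkN1) x12 <- x12 + 1
      if (spkN2) y12 <- y12 + 1
      c12 <- c12 * dc + inc12
      r1 <- r1 * dr; if (rel1) r1 <- r1 + C_r
      rc <- r1 * c12
      w12n <- w12 + dt * (g12 * rc - (w12 - w0) / tau_w)
      w12 <- if (w12n < 0) 0 else w12n
      g12 <- g12 + dtl * rc

      x34 <- x34 * dxp; y34 <- y34 * dxm
      inc34 <- 0
      if (spkN3) inc34 <- inc34 + A_minus * y34
      if (spkN4) inc34 <- inc34 + A_plus * x34
      if (spkN3) x34 <- x34 + 1
      if (spkN4) y34 <- y34 + 1
      c34 <- c34 * dc + inc34
      r2 <- r2 * dr; if (rel2) r2 <- r2 + C_r
      rc <- r2 * c34
      w34n <- w34 + dt * (g34 * rc - (w34 - w0) / tau_w)
      w34 <- if (w34n < 0) 0 else w34n
      g34 <- g34 + dtl * rc
    } else {
      ## reward variables still decay/jump so release dynamics are observable
      r1 <- r1 * dr; if (rel1) r1 <- r1 + C_r
      r2 <- r2 * dr; if (rel2) r2 <- r2 + C_r
    }

    if (record)
      rec[k, ] <- c(t, vL, vR, vN1, vN2, vN3, vN4, vOut, vStop, vR1, vR2,
                    w12, w34, g12, g34, c12, c34, r1, r2,
                    as.numeric(spkOut), as.numeric(rel1), as.numeric(rel2))
  }

  ## repack
  st$vL <- vL; st$vR <- vR
  st$vN1 <- vN1; st$refN1 <- refN1; st$vN2 <- vN2; st$refN2 <- refN2
  st$vN3 <- vN3; st$refN3 <- refN3; st$vN4 <- vN4; st$refN4 <- refN4
  st$vOut <- vOut; st$refOut <- refOut; st$vStop <- vStop; st$refStop <- refStop
  st$vR1 <- vR1; st$refR1 <- refR1; st$vR2 <- vR2; st$refR2 <- refR2
  st$sy12 <- sy12; st$sy34 <- sy34; st$s2o <- s2o; st$s4o <- s4o
  st$s2r1 <- s2r1; st$s4r2 <- s4r2; st$sLs <- sLs; st$sRs <- sRs
  st$x12 <- x12; st$y12 <- y12; st$c12 <- c12; st$w12 <- w12; st$g12 <- g12
  st$x34 <- x34; st$y34 <- y34; st$c34 <- c34; st$w34 <- w34; st$g34 <- g34
  st$r1 <- r1; st$r2 <- r2; st$t <- t

  list(state = st,
       counts = list(out = cOut, stop = cStop, n2 = cN2, n4 = cN4,
                     left = cL, right = cRt, rel1 = cRel1, rel2 = cRel2),
       first_release_time = first_rel_t,
       record = rec)
}

#' Advance the whole network by a fixed duration at constant sensor input
#'
#' Runs the clock-driven loop (all neurons, synapses, traces, eligibility,
#' reward channels and both plastic weights) for `duration` ms with the
#' sensors held at the given distances.
#'
#' @param spec Calibrated `snn_spec`.
#' @param state Runtime state from [network_init()] (or a previous run).
#' @param d_left,d_right Sensor distances, cm.
#' @param duration Simulated time, ms.
#' @param plastic Logical: apply the learning rule (default `TRUE`).
#' @param record Logical: return the per-step telemetry matrix (default
#'   `FALSE`; memory grows with `duration/dt`).
#' @return List with `state`, per-run spike/release `counts`,
#'   `first_release_time` (ms, `NA` if none) and `record` (matrix or `NULL`).
#' @export
run_network <- function(spec, state, d_left, d_right, duration,
                        plastic = TRUE, record = FALSE) {
  n_steps <- round(duration / spec$dt)
  stopifnot(n_steps >= 1)
  run_chunk(spec, state, d_left, d_right, n_steps,
            plastic = plastic, record = record)
}

#' Advance the whole network by one clock step
#'
#' Single-step wrapper around the same update rules as [run_network()];
#' convenient for inspecting per-step telemetry.
#'
#' @param spec Calibrated `snn_spec`.
#' @param state Runtime state.
#' @param d_left,d_right Sensor distances, cm.
#' @param dt Step size, ms; must equal `spec$dt`.
#' @return List with `state` and a one-row `telemetry` matrix (membrane
#'   potentials, weights, learning rates, eligibility, reward values,
#'   Out spike and release flags).
#' @export
network_step <- function(spec, state, d_left, d_right, dt = spec$dt) {
  if (!isTRUE(all.equal(dt, spec$dt)))
    stop("network_step must use the spec's clock (dt = spec$dt)")
  out <- run_chunk(spec, state, d_left, d_right, 1L, record = TRUE)
  list(state = out$state, telemetry = out$record)
}

## ---------------------------------------------------------------------------
## calibration

## Constant bias giving a leaky neuron an exact discrete firing period.
## With the exponential-leak / Euler-drive update, the membrane after n
## drive steps from rest is b * (1 - a^n) / (1 - a) with a = exp(-dt/tau)
## and b = dt*R*I/tau, so the bias window for threshold crossing exactly at
## step n is closed-form; the midpoint is returned.
lif_bias_for_period <- function(np, dt, period_ms) {
  a <- exp(-dt / np$tau)
  ref_steps <- round(np$t_ref / dt)
  n <- round(period_ms / dt) - ref_steps
  stopifnot(n >= 2)
  vspan <- np$v_th - np$v_rest
  b_lo <- vspan * (1 - a) / (1 - a^n)
  b_hi <- vspan * (1 - a) / (1 - a^(n - 1))
  b <- (b_lo + b_hi) / 2
  b * np$tau / (dt * np$R)
}

## smallest W in [lo, hi] for which pred(W) is TRUE (pred monotone in W)
bisect_min_weight <- function(pred, lo, hi, tol = 0.25) {
  if (!pred(hi)) return(NA_real_)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pred(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Calibrate the controller's operating points
#'
#' Fixes every inferred constant of the architecture deterministically:
#'
#' * encoder gain (fixed at 10 in [encoder_params()]) so the encoders fire
#'   at 25 Hz at `d_max` and 50 Hz at `d_min`;
#' * pacemaker bias for N1/N3 giving an exact 25 Hz discrete period
#'   (closed form);
#' * a constant bias to Out holding the baseline rate at ~12 Hz (closed
#'   form; at baseline the N2/N4 pulse trains cancel exactly, so Out is
#'   bias-driven);
#' * the relay drive gain (fixed) that converts the dimensionless plastic
#'   weight into a suprathreshold relay drive;
#' * the dopamine-gate drive gain (closed form: membrane plateau of 25 mV
#'   at `d_min`) and the gate pulse weight (bisection on simulated release
#'   counts) so that releases require near-`d_min` sensor drive AND
#'   concurrent relay spikes — neither alone suffices;
#' * the Stop-side weight (bisection) so one encoder at 50 Hz never fires
#'   Stop but bilateral 50 Hz input fires it within 500 ms.
#'
#' With `verify = TRUE` (default) every setpoint is re-checked by
#' simulation and a failure is reported with the offending setpoint.
#'
#' @param spec An `snn_spec` from [build_network()].
#' @param verify Logical: run the verification simulations (default `TRUE`).
#' @return The calibrated spec, with `spec$calib` filled and
#'   `spec$calib$report` holding the measured setpoints.
#' @export
calibrate_network <- function(spec, verify = TRUE) {
  dt <- spec$dt
  ep <- spec$encoder
  lifn <- spec$neurons$N1

  cal <- list(
    pacemaker_rate_hz = 25,
    pacemaker_bias = lif_bias_for_period(lifn, dt, 1000 / 25),
    out_rate_hz = 12,
    out_bias = NA_real_,
    W_out_inh = 4,
    W_out_exc = 4,
    relay_drive_gain = NA_real_,
    relay_margin_w = 0.01,
    gate_plateau_mv = 28.5,
    gate_drive_gain = 28.5 / (lifn$R * raw_distance_current(ep, ep$d_min)),
    gate_pulse_weight = NA_real_,
    W_stop = NA_real_)
  spec$calib <- cal

  ## Relay drive gain: the discriminative event is the appearance of a
  ## second relay spike per pacemaker period when a plastic weight rises.
  ## The gain is placed so that this threshold sits a margin of
  ## `relay_margin_w` above the baseline weight w0: at w0 each relay fires
  ## exactly one spike per period, and a small weight increase flips its
  ## channel into the two-spike regime (strong, correctly signed drive at
  ## Out), before any weaker timing effect can act.
  relay_doubles <- function(G, wval) {
    sp <- spec
    sp$calib$relay_drive_gain <- G
    sp$calib$out_bias <- 0
    sp$calib$gate_pulse_weight <- 0
    sp$calib$W_stop <- 0
    st <- network_init(sp)
    st$w12 <- wval
    cnt <- run_network(sp, st, ep$d_max, ep$d_max, 1000,
                       plastic = FALSE)$counts
    ## one spike per pacemaker period is 25/s; the two-spike regime is 50/s
    cnt$n2 >= 1.5 * cal$pacemaker_rate_hz
  }
  G_boundary <- bisect_min_weight(function(G) relay_doubles(G, 1),
                                  lo = 60, hi = 400, tol = 0.05)
  if (is.na(G_boundary))
    stop("calibration failed: relay never reaches the two-spike regime")

  ## Refinement: the relay membrane before its first spike is linear in the
  ## weight, so that spike's timing holds until w reaches 30/v_last (v_last
  ## = membrane one step before the crossing). The doubling threshold is
  ## 30/v_peak2 (v_peak2 = post-refractory membrane peak). The gain is
  ## chosen so the doubling threshold lies a clear distance BELOW the
  ## timing-shift threshold: the first observable response to a rising
  ## weight is then always the strong, correctly-signed burst doubling,
  ## never a sub-threshold timing transient.
  relay_margins <- function(G) {
    sp <- spec
    sp$calib$relay_drive_gain <- G
    sp$calib$out_bias <- 0
    sp$calib$gate_pulse_weight <- 0
    sp$calib$W_stop <- 0
    rec <- run_network(sp, network_init(sp), ep$d_max, ep$d_max, 400,
                       plastic = FALSE, record = TRUE)$record
    v <- rec[, "vN2"]
    ## settled crossings: membrane falls to reset from a high value
    k <- which(v[-1] == spec$neurons$N2$v_rest & v[-length(v)] > 20) + 1L
    k <- k[k > 2000]
    if (length(k) < 2) return(NULL)
    vth <- spec$neurons$N2$v_th
    v_last <- max(v[k - 1])
    seg <- v[(k[1] + 25):(k[2] - 30)]        # between burst and next pulse
    v_peak2 <- max(seg)
    list(w_timing = vth / v_last, w_double = vth / v_peak2)
  }
  best <- NULL
  for (mw in seq(0.005, 0.025, by = 0.001)) {
    m <- relay_margins(G_boundary / (1 + mw))
    if (is.null(m)) next
    gap <- m$w_timing - m$w_double
    if (is.null(best) || gap > best$gap)
      best <- list(G = G_boundary / (1 + mw), gap = gap,
                   w_double = m$w_double, w_timing = m$w_timing)
  }
  if (is.null(best))
    stop("calibration failed: relay margins could not be measured")
  spec$calib$relay_drive_gain <- best$G
  spec$calib$relay_margin_w <- best$w_double - 1
  if (relay_doubles(best$G, 1))
    stop("calibration failed: relay fires twice per period at baseline weight")
  if (!relay_doubles(best$G, best$w_double + 0.005))
    stop("calibration failed: relay margin did not land above w0")

  ## Out bias: at baseline the excitatory (N2) and inhibitory (N4) pulse
  ## trains are synchronous and equally weighted, so they cancel exactly
  ## and Out is purely bias-driven; the closed-form bias for a 12 Hz
  ## discrete period is exact.
  spec$calib$out_bias <-
    lif_bias_for_period(lifn, dt, round((1000 / cal$out_rate_hz) / dt) * dt)

  sim_counts <- function(dl, dr, duration, W_p = 0, W_stop = 0, w = 1) {
    sp <- spec
    sp$calib$gate_pulse_weight <- W_p
    sp$calib$W_stop <- W_stop
    st <- network_init(sp)
    st$w12 <- w; st$w34 <- w
    run_network(sp, st, dl, dr, duration, plastic = FALSE)$counts
  }

  ## gate pulse weight: releases required at (d_min drive + relay spikes)
  ## within 200 ms; none at baseline drive. Probe horizons are short; the
  ## final choice is verified at the full contract horizons below.
  w_gate_lo <- bisect_min_weight(
    function(W) sim_counts(ep$d_min, ep$d_max, 200, W_p = W)$rel2 >= 1,
    lo = 0, hi = 400)
  ## the upper bound must hold in the doubled-relay regime too (weights
  ## above the two-spike threshold at maximum range), or reward would
  ## self-sustain after an encounter and the weight would never relax
  w_high <- 1 + 5 * cal$relay_margin_w
  w_gate_hi <- bisect_min_weight(
    function(W) {
      cnt1 <- sim_counts(ep$d_max, ep$d_max, 1000, W_p = W)
      cnt2 <- sim_counts(ep$d_max, ep$d_max, 1000, W_p = W, w = w_high)
      cnt1$rel1 + cnt1$rel2 + cnt2$rel1 + cnt2$rel2 >= 1
    },
    lo = 0, hi = 400)
  if (is.na(w_gate_lo))
    stop("calibration failed: no gate pulse weight yields releases at d_min")
  if (!is.na(w_gate_hi) && w_gate_hi <= w_gate_lo)
    stop("calibration failed: gate conjunction window is empty ",
         "(baseline releases before d_min releases)")
  ## placed in the upper part of the conjunction window: each relay spike
  ## then triggers a short burst of releases (a vigorous dopamine response
  ## near the obstacle) while baseline silence keeps a 25% margin
  spec$calib$gate_pulse_weight <-
    if (is.na(w_gate_hi)) 1.5 * w_gate_lo else
      w_gate_lo + 0.75 * (w_gate_hi - w_gate_lo)

  ## Stop weight: bilateral 50 Hz must fire within 500 ms, unilateral never
  w_stop_lo <- bisect_min_weight(
    function(W) sim_counts(ep$d_min, ep$d_min, 500, W_stop = W)$stop >= 1,
    lo = 0, hi = 600)
  w_stop_hi <- bisect_min_weight(
    function(W) sim_counts(ep$d_min, ep$d_max, 1000, W_stop = W)$stop >= 1,
    lo = 0, hi = 600)
  if (is.na(w_stop_lo))
    stop("calibration failed: no Stop weight yields bilateral braking")
  if (!is.na(w_stop_hi) && w_stop_hi <= w_stop_lo)
    stop("calibration failed: brake conjunction window is empty")
  spec$calib$W_stop <-
    if (is.na(w_stop_hi)) 1.5 * w_stop_lo else (w_stop_lo + w_stop_hi) / 2

  if (verify) spec <- verify_calibration(spec)
  spec
}

## re-check every setpoint by simulation; attach the report or fail loudly
verify_calibration <- function(spec) {
  ep <- spec$encoder
  fail <- character(0)
  report <- list()

  enc_rate <- function(d) {
    np <- spec$neurons$Left
    st <- neuron_state(np)
    I <- encode_distance(ep, d, d)[["I_left"]]
    n <- 0L
    steps <- round(4000 / spec$dt)
    for (k in seq_len(steps)) {
      up <- if_step(np, st, I, k * spec$dt, spec$dt)
      st <- up$state
      if (up$spiked) n <- n + 1L
    }
    n / 4
  }
  report$encoder_rate_dmax <- enc_rate(ep$d_max)
  report$encoder_rate_dmin <- enc_rate(ep$d_min)
  if (abs(report$encoder_rate_dmax - 25) > 2.5)
    fail <- c(fail, sprintf("encoder at d_max: %.2f Hz (target 25)",
                            report$encoder_rate_dmax))
  if (abs(report$encoder_rate_dmin - 50) > 5)
    fail <- c(fail, sprintf("encoder at d_min: %.2f Hz (target 50)",
                            report$encoder_rate_dmin))

  base <- run_network(spec, network_init(spec), ep$d_max, ep$d_max, 4000)
  report$pacemaker_rate <- base$counts$n2 * 0  # placeholder, filled below
  report$baseline_out_rate <- base$counts$out / 4
  report$baseline_releases <- base$counts$rel1 + base$counts$rel2
  report$baseline_w_drift <- max(abs(base$state$w12 - spec$plasticity$w0),
                                 abs(base$state$w34 - spec$plasticity$w0))
  if (report$baseline_out_rate < spec$bands[["low_hz"]] ||
      report$baseline_out_rate > spec$bands[["high_hz"]])
    fail <- c(fail, sprintf("baseline Out rate %.2f Hz outside straight band",
                            report$baseline_out_rate))
  if (report$baseline_releases > 0)
    fail <- c(fail, sprintf("%d reward releases at baseline",
                            report$baseline_releases))
  if (report$baseline_w_drift > 0.01 * spec$plasticity$w0)
    fail <- c(fail, "weights drift more than 1% from w0 at baseline")

  ## pacemaker rate via a bias-driven leaky unit alone
  pm <- spec$neurons$N1
  st <- neuron_state(pm)
  n <- 0L
  for (k in seq_len(round(4000 / spec$dt))) {
    up <- lif_step(pm, st, spec$calib$pacemaker_bias, k * spec$dt, spec$dt)
    st <- up$state
    if (up$spiked) n <- n + 1L
  }
  report$pacemaker_rate <- n / 4
  if (abs(report$pacemaker_rate - 25) > 1)
    fail <- c(fail, sprintf("pacemaker rate %.2f Hz (target 25)",
                            report$pacemaker_rate))

  ## gate contract
  g_on <- run_network(spec, network_init(spec), ep$d_min, ep$d_max, 200,
                      plastic = FALSE)
  report$gate_releases_200ms <- g_on$counts$rel2
  if (g_on$counts$rel2 < 1)
    fail <- c(fail, "gate: no release within 200 ms at d_min drive")
  g_off <- run_network(spec, network_init(spec), ep$d_max, ep$d_max, 5000,
                       plastic = FALSE)
  report$gate_baseline_releases_5s <- g_off$counts$rel1 + g_off$counts$rel2
  if (report$gate_baseline_releases_5s > 0)
    fail <- c(fail, "gate: releases at baseline drive over 5 s")
  st_hi <- network_init(spec)
  st_hi$w12 <- st_hi$w34 <- 1 + 5 * spec$calib$relay_margin_w
  g_off2 <- run_network(spec, st_hi, ep$d_max, ep$d_max, 5000,
                        plastic = FALSE)
  report$gate_doubled_baseline_releases_5s <-
    g_off2$counts$rel1 + g_off2$counts$rel2
  if (report$gate_doubled_baseline_releases_5s > 0)
    fail <- c(fail, "gate: releases at baseline drive with doubled relays")

  ## brake contract
  b_one <- run_network(spec, network_init(spec), ep$d_min, ep$d_max, 5000,
                       plastic = FALSE)
  report$stop_unilateral_5s <- b_one$counts$stop
  if (b_one$counts$stop > 0)
    fail <- c(fail, "brake: Stop fires under unilateral 50 Hz input")
  b_two <- run_network(spec, network_init(spec), ep$d_min, ep$d_min, 500,
                       plastic = FALSE)
  report$stop_bilateral_500ms <- b_two$counts$stop
  if (b_two$counts$stop < 1)
    fail <- c(fail, "brake: Stop silent under bilateral 50 Hz input (500 ms)")

  if (length(fail))
    stop(paste(c("calibration verification failed:", fail),
               collapse = "\n  - "))
  spec$calib$report <- report
  spec
}
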