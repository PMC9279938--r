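## Point-neuron models on a fixed simulation clock.
##
## Unit system used throughout the package: mV / ms / nA / MOhm, so that
## R * I (MOhm * nA) is directly a potential in mV and all time constants
## are in ms.  Integration is first order: exact exponential update for the
## pure-decay (leak) term, forward Euler for the drive term, with a default
## clock of dt = 0.1 ms.

#' Neuron parameter set
#'
#' Parameters of a single integrate-and-fire unit. Two model kinds are
#' supported: `"integrator"` (perfect integrator, used to encode sensor
#' distances into spike trains; no refractory period) and `"leaky"`
#' (relaxes toward the resting potential; 2 ms refractory period by
#' default). Membrane dynamics are
#' \deqn{\tau \, dv/dt = v_{rest} + R I(t)}{tau dv/dt = v_rest + R I(t)}
#' for the integrator and
#' \deqn{\tau_m \, dv/dt = -(v - v_{rest}) + R I(t)}{tau_m dv/dt = -(v - v_rest) + R I(t)}
#' for the leaky unit. When `v` reaches `v_th` a spike is fired in that
#' step and `v` is reset to `v_rest`. Note the integrator drift includes a
#' constant `v_rest/tau` term; with the default `v_rest = 0` this is the
#' standard perfect integrator.
#'
#' @param model_kind `"integrator"` or `"leaky"`.
#' @param tau Membrane time constant, ms (default 1 for integrator, 5 for leaky).
#' @param R Membrane resistance, MOhm.
#' @param v_rest Resting potential, mV.
#' @param v_th Threshold potential, mV; must exceed `v_rest`.
#' @param t_ref Refractory duration, ms; forced to 0 for integrators.
#' @param bias_current Constant injected current, nA.
#' @return An object of class `neuron_params`.
#' @examples
#' np <- neuron_params("leaky")
#' np$tau
#' @export
neuron_params <- function(model_kind = c("leaky", "integrator"),
                          tau = NULL, R = 1, v_rest = 0, v_th = 30,
                          t_ref = NULL, bias_current = 0) {
  model_kind <- match.arg(model_kind)
  if (is.null(tau)) tau <- if (model_kind == "integrator") 1 else 5
  if (is.null(t_ref)) t_ref <- if (model_kind == "integrator") 0 else 2
  if (model_kind == "integrator" && t_ref != 0)
    stop("integrator neurons have no refractory period (t_ref must be 0)")
  stopifnot(is.numeric(tau), length(tau) == 1, is.finite(tau), tau > 0,
            is.numeric(R), length(R) == 1, is.finite(R), R > 0,
            is.finite(v_rest), is.finite(v_th), is.finite(t_ref),
            t_ref >= 0, is.finite(bias_current))
  if (v_th <= v_rest) stop("v_th must be greater than v_rest")
  structure(list(model_kind = model_kind, tau = tau, R = R,
                 v_rest = v_rest, v_th = v_th, t_ref = t_ref,
                 bias_current = bias_current),
            class = "neuron_params")
}

#' Fresh neuron state
#'
#' @param params A [neuron_params()] object.
#' @return List with membrane potential `v` (at rest), `refractory_remaining`
#'   (ms) and the ordered vector `spike_times` (ms).
#' @export
neuron_state <- function(params) {
  list(v = params$v_rest, refractory_remaining = 0, spike_times = numeric(0))
}

check_step_args <- function(I_in, dt) {
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive finite number")
  if (!is.numeric(I_in) || length(I_in) != 1 || !is.finite(I_in))
    stop("I_in must be a single finite number")
  invisible(TRUE)
}

#' Advance a perfect-integrator neuron by one step
#'
#' Forward-Euler update of the integrator equation; threshold crossing fires
#' a spike at the end of the step and resets `v` to `v_rest`. Integrators
#' have no refractory period. Any encoder gain must already be folded into
#' `I_in`.
#'
#' @param params [neuron_params()] with `model_kind = "integrator"`.
#' @param state Neuron state as from [neuron_state()].
#' @param I_in Injected current, nA (added to `bias_current`).
#' @param t Current time, ms (used only to record spike times).
#' @param dt Step size, ms.
#' @return `list(state = <new state>, spiked = <logical>)`.
#' @examples
#' np <- neuron_params("integrator")
#' st <- neuron_state(np)
#' if_step(np, st, I_in = 0.75, t = 0, dt = 0.1)$state$v
#' @export
if_step <- function(params, state, I_in, t, dt) {
  stopifnot(params$model_kind == "integrator")
  check_step_args(I_in, dt)
  I <- I_in + params$bias_current
  v <- state$v + dt * (params$v_rest + params$R * I) / params$tau
  spiked <- v >= params$v_th
  if (spiked) {
    v <- params$v_rest
    state$spike_times <- c(state$spike_times, t)
  }
  state$v <- v
  list(state = state, spiked = spiked)
}

#' Advance a leaky integrate-and-fire neuron by one step
#'
#' Exact exponential update of the leak plus forward-Euler drive. While the
#' refractory clock is running, input current is ignored and `v` is held at
#' `v_rest`; on a threshold crossing the neuron spikes, `v` resets and the
#' refractory clock is set to `t_ref`.
#'
#' @inheritParams if_step
#' @return `list(state = <new state>, spiked = <logical>)`.
#' @examples
#' np <- neuron_params("leaky")
#' st <- neuron_state(np)
#' st$v <- 10
#' # relaxes toward rest with tau_m = 5 ms
#' for (k in 1:50) st <- lif_step(np, st, 0, k * 0.1, 0.1)$state
#' st$v  # ~ 10/e
#' @export
lif_step <- function(params, state, I_in, t, dt) {
  stopifnot(params$model_kind == "leaky")
  check_step_args(I_in, dt)
  if (state$refractory_remaining > 0) {
    state$refractory_remaining <- max(0, state$refractory_remaining - dt)
    state$v <- params$v_rest
    return(list(state = state, spiked = FALSE))
  }
  I <- I_in + params$bias_current
  decay <- exp(-dt / params$tau)
  v <- params$v_rest + (state$v - params$v_rest) * decay +
    dt * params$R * I / params$tau
  spiked <- v >= params$v_th
  if (spiked) {
    v <- params$v_rest
    state$refractory_remaining <- params$t_ref
    state$spike_times <- c(state$spike_times, t)
  }
  state$v <- v
  list(state = state, spiked = spiked)
}

#' Synapse parameter set
#'
#' Exponential current-based synapse: on each presynaptic spike the synaptic
#' current jumps by `weight * gain_A` and otherwise decays with time
#' constant `tau_s`. Inhibitory synapses deliver their current negated to
#' the target neuron.
#'
#' @param tau_s Synaptic current time constant, ms (default 10).
#' @param gain_A Per-spike accumulation constant (default 0.5).
#' @param polarity `"excitatory"` or `"inhibitory"`.
#' @return An object of class `synapse_params`.
#' @export
synapse_params <- function(tau_s = 10, gain_A = 0.5,
                           polarity = c("excitatory", "inhibitory")) {
  polarity <- match.arg(polarity)
  stopifnot(is.numeric(tau_s), length(tau_s) == 1, is.finite(tau_s), tau_s > 0,
            is.numeric(gain_A), length(gain_A) == 1, is.finite(gain_A))
  structure(list(tau_s = tau_s, gain_A = gain_A, polarity = polarity),
            class = "synapse_params")
}

#' Fresh synapse state
#' @param params A [synapse_params()] object (unused beyond validation).
#' @return List with synaptic current `I_syn` (nA), starting at 0.
#' @export
synapse_state <- function(params) {
  stopifnot(inherits(params, "synapse_params"))
  list(I_syn = 0)
}

#' Advance a synapse by one step
#'
#' The current decays exponentially with `tau_s`; if the presynaptic neuron
#' spiked this step, `weight * gain_A` is added after the decay. The sign
#' flip for inhibitory synapses happens at delivery (see
#' [synapse_current()]), not in the stored state.
#'
#' @param params [synapse_params()].
#' @param state Synapse state as from [synapse_state()].
#' @param pre_spiked Logical: did the presynaptic neuron fire this step?
#' @param weight Synaptic weight (dimensionless).
#' @param dt Step size, ms.
#' @return Updated state.
#' @export
synapse_step <- function(params, state, pre_spiked, weight, dt) {
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive finite number")
  I <- state$I_syn * exp(-dt / params$tau_s)
  if (isTRUE(pre_spiked)) I <- I + weight * params$gain_A
  state$I_syn <- I
  state
}

#' Current delivered by a synapse to its target
#'
#' @param params [synapse_params()].
#' @param state Synapse state.
#' @return `I_syn`, negated for inhibitory polarity.
#' @export
synapse_current <- function(params, state) {
  if (params$polarity == "inhibitory") -state$I_syn else state$I_syn
}
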