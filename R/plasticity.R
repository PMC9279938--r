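## Learning dynamics: pair-based STDP traces, eligibility traces, reward
## variables, the classic reward-modulated STDP rule, and the improved rule
## (weight decay toward baseline + reward-driven adaptive learning rate).
##
## Within one clock step the update order is: (1) neurons spike, (2) traces
## decay, (3) the STDP increment is evaluated with the pre-jump traces,
## (4) traces jump, (5) eligibility and reward update, (6) the weight rule.
## A coincident pre/post pair (dt = 0) therefore contributes nothing.

#' Plasticity parameter set
#'
#' Constants for one plastic synapse under the three-factor rule:
#' trace amplitudes/time constants of pair-based STDP, the eligibility time
#' constant, the baseline weight and weight-decay time constant, and the
#' learning-rate dynamics (`gamma' = l * r * c`).
#'
#' `tau_w` (weight relaxation toward `w0`) and `gamma0` (initial learning
#' rate) are model-level choices exposed here: `tau_w = 1000` ms makes an
#' exercised weight return to baseline a few seconds after reward ceases,
#' and `gamma0` sets the speed of the first learning episode (see the
#' methods vignette for how its default was fixed).
#'
#' @param A_plus,A_minus STDP amplitudes (defaults +1 / -1).
#' @param tau_plus,tau_minus Pre/post trace time constants, ms (default 10).
#' @param tau_c Eligibility trace time constant, ms (default 10).
#' @param tau_w Weight decay time constant, ms (default 1000); `Inf` disables
#'   the decay term.
#' @param w0 Baseline weight (default 1).
#' @param l Learning-rate gain constant (default 3e-5).
#' @param gamma0 Initial learning rate (default 1.2e-3).
#' @return An object of class `plasticity_params`.
#' @export
plasticity_params <- function(A_plus = 1, A_minus = -1,
                              tau_plus = 10, tau_minus = 10, tau_c = 10,
                              tau_w = 1000, w0 = 1, l = 3e-5,
                              gamma0 = 1.2e-3) {
  stopifnot(is.finite(A_plus), is.finite(A_minus),
            A_minus <= 0, A_plus >= 0,
            is.finite(tau_plus), tau_plus > 0,
            is.finite(tau_minus), tau_minus > 0,
            is.finite(tau_c), tau_c > 0,
            tau_w > 0,                      # Inf allowed
            is.finite(w0), w0 >= 0,
            is.finite(l), l >= 0,
            is.finite(gamma0), gamma0 >= 0)
  structure(list(A_plus = A_plus, A_minus = A_minus, tau_plus = tau_plus,
                 tau_minus = tau_minus, tau_c = tau_c, tau_w = tau_w,
                 w0 = w0, l = l, gamma0 = gamma0),
            class = "plasticity_params")
}

#' Fresh plastic-synapse state
#'
#' @param params A [plasticity_params()] object.
#' @return List with weight `w` (= `w0`), presynaptic trace `x`, postsynaptic
#'   trace `y`, eligibility trace `c` and learning rate `gamma` (= `gamma0`).
#' @export
plastic_synapse_state <- function(params) {
  list(w = params$w0, x = 0, y = 0, c = 0, gamma = params$gamma0)
}

#' Decay and jump the pre/post spike traces
#'
#' `x` and `y` decay exponentially with `tau_plus` / `tau_minus` and jump by
#' exactly 1 on a pre- / postsynaptic spike.
#'
#' @param p [plasticity_params()].
#' @param s Plastic-synapse state.
#' @param pre_spiked,post_spiked Logicals for this step.
#' @param dt Step size, ms.
#' @return Updated state.
#' @export
update_traces <- function(p, s, pre_spiked, post_spiked, dt) {
  stopifnot(dt > 0)
  s$x <- s$x * exp(-dt / p$tau_plus) + as.numeric(isTRUE(pre_spiked))
  s$y <- s$y * exp(-dt / p$tau_minus) + as.numeric(isTRUE(post_spiked))
  s
}

#' Pair-based STDP increment for the current step
#'
#' Must be called after the traces have decayed for this step but before
#' they jump, so that a coincident pair contributes nothing. Returns
#' `A_minus * y` if a presynaptic spike occurred this step plus
#' `A_plus * x` if a postsynaptic spike occurred; 0 otherwise. This is the
#' STDP term consumed by the eligibility trace.
#'
#' @inheritParams update_traces
#' @return The (dimensionless) increment.
#' @export
stdp_increment <- function(p, s, pre_spiked, post_spiked) {
  inc <- 0
  if (isTRUE(pre_spiked)) inc <- inc + p$A_minus * s$y
  if (isTRUE(post_spiked)) inc <- inc + p$A_plus * s$x
  inc
}

#' All-pairs STDP total (test oracle)
#'
#' Sums `A_plus * exp(-dt/tau_plus)` over all spike pairs with
#' `dt = t_post - t_pre > 0` and `A_minus * exp(dt/tau_minus)` over pairs
#' with `dt < 0`; coincident pairs contribute nothing. Used as an
#' independent oracle for the trace-based recursion, which is the all-pairs
#' sum in recursive form.
#'
#' @param pre_times,post_times Numeric vectors of spike times, ms.
#' @param p [plasticity_params()].
#' @return Total weight change (dimensionless).
#' @export
brute_force_stdp <- function(pre_times, post_times, p) {
  stopifnot(all(is.finite(pre_times)), all(is.finite(post_times)))
  if (length(pre_times) == 0 || length(post_times) == 0) return(0)
  total <- 0
  for (tpost in post_times) {
    dtv <- tpost - pre_times
    total <- total + p$A_plus * sum(exp(-dtv[dtv > 0] / p$tau_plus))
    total <- total + p$A_minus * sum(exp(dtv[dtv < 0] / p$tau_minus))
  }
  total
}

#' Decay the eligibility trace and accumulate the STDP increment
#'
#' @param p [plasticity_params()].
#' @param s Plastic-synapse state.
#' @param increment Output of [stdp_increment()] for this step.
#' @param dt Step size, ms.
#' @return Updated state.
#' @export
update_eligibility <- function(p, s, increment, dt) {
  stopifnot(dt > 0)
  s$c <- s$c * exp(-dt / p$tau_c) + increment
  s
}

#' Reward-channel state
#'
#' The decaying reward variable fed by a dopaminergic release unit: each
#' release adds `C_r`, and `r` decays exponentially with `tau_r`.
#'
#' @param tau_r Decay constant, ms (default 2).
#' @param C_r Per-release increment (default 0.07).
#' @return List with `r` (= 0), `tau_r`, `C_r` and the ordered
#'   `release_times` vector (ms).
#' @export
reward_state <- function(tau_r = 2, C_r = 0.07) {
  stopifnot(is.finite(tau_r), tau_r > 0, is.finite(C_r), C_r >= 0)
  list(r = 0, tau_r = tau_r, C_r = C_r, release_times = numeric(0))
}

#' Decay the reward variable and apply this step's releases
#'
#' @param rs Reward state from [reward_state()].
#' @param n_releases Number of release events this step (>= 0).
#' @param dt Step size, ms.
#' @param t Current time, ms (recorded per release; optional).
#' @return Updated reward state.
#' @export
update_reward <- function(rs, n_releases, dt, t = NA_real_) {
  stopifnot(dt > 0, n_releases >= 0)
  rs$r <- rs$r * exp(-dt / rs$tau_r) + rs$C_r * n_releases
  if (n_releases > 0 && !is.na(t))
    rs$release_times <- c(rs$release_times, rep(t, n_releases))
  rs
}

#' Classic reward-modulated STDP weight step
#'
#' `w' = gamma * r * c` with a fixed learning rate; reference rule used for
#' limit tests of the improved rule.
#'
#' @param s Plastic-synapse state (uses its `gamma`).
#' @param r Current reward value.
#' @param dt Step size, ms.
#' @return Updated state.
#' @export
classic_rstdp_step <- function(s, r, dt) {
  stopifnot(dt > 0)
  s$w <- s$w + dt * s$gamma * r * s$c
  s
}

#' Improved rule: reward-gated weight change, baseline decay, adaptive rate
#'
#' `w' = gamma(t) * r * c - (w - w0)/tau_w` (weight clamped at >= 0) and
#' `gamma' = l * r * c`. With reward absent the weight relaxes to `w0`
#' while `gamma` keeps the memory of past learning.
#'
#' @param p [plasticity_params()].
#' @param s Plastic-synapse state.
#' @param r Current reward value.
#' @param dt Step size, ms.
#' @return Updated state.
#' @export
improved_rule_step <- function(p, s, r, dt) {
  stopifnot(dt > 0)
  rc <- r * s$c
  w <- s$w + dt * (s$gamma * rc - (s$w - p$w0) / p$tau_w)
  s$w <- if (w < 0) 0 else w
  s$gamma <- s$gamma + dt * p$l * rc
  s
}
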