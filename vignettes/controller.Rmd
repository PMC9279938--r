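---
title: "A reward-modulated spiking controller for obstacle avoidance: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reward-modulated spiking controller for obstacle avoidance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`snnbot` is a clock-driven simulator for a small spiking network that learns
to steer a mobile robot away from obstacles. This vignette is the package's
account of its science: the neuron, synapse and plasticity models and their
assumptions; the ten-neuron controller and how its free constants were
calibrated; what the synthetic 2D environment does and does not emulate; and
the design decisions taken where the published description left the design
open.

## Neuron and synapse models

All dynamics are integrated on a shared clock with `dt = 0.1` ms in a fixed
unit system of mV / ms / nA / MΩ, so that a current of `I` nA through a
membrane resistance of `R` MΩ contributes `R*I` mV. Two point-neuron models
are used:

* **Perfect integrator** (`model_kind = "integrator"`), used by the two
  distance encoders: `tau dv/dt = v_rest + R I(t)` with `tau = 1` ms,
  `R = 1` MΩ. The drift is written with the `v_rest` term deliberately:
  with the default `v_rest = 0` it is the textbook integrator, but the
  equation is integrated literally so a nonzero resting potential would add
  a constant drift. There is no refractory period.
* **Leaky integrate-and-fire** (`model_kind = "leaky"`), used by every other
  unit: `tau_m dv/dt = -(v - v_rest) + R I(t)` with `tau_m = 5` ms and a
  2 ms refractory period during which input is ignored and the membrane is
  held at rest.

Both share a 30 mV threshold; a spike is registered in the step in which
`v >= v_th` and the membrane resets to `v_rest` in the same step. Integration
is first order: the leak is applied as an exact exponential factor
`exp(-dt/tau)` and the drive as a forward-Euler increment `dt*R*I/tau`. The
drive term gives the scheme its only appreciable bias — a steady state
overestimated by a factor `(dt/tau)/(1 - exp(-dt/tau)) ≈ 1 + dt/(2 tau)`
(about 1% at the default clock); the test suite pins this with a
dt-halving bound of `R*I*dt/(2*tau)` on whole trajectories.

Synapses are exponential current-based: each presynaptic spike adds
`weight * A` (accumulation constant `A = 0.5`) to a synaptic current that
decays with `tau_s = 10` ms; inhibitory synapses deliver the negated
current. Spike propagation has a one-step delay — spikes fired in step `n`
enter the target's membrane update in step `n + 1` — which makes the update
order of a step deterministic: neurons, then synapses, then plasticity. The
model the synapse implements is a first-order exponential current (the
"alpha" naming sometimes attached to this equation describes a second-order
kernel; the equation, not the name, is implemented).

## Plasticity: three-factor learning with an adaptive learning rate

Each of the two plastic synapses keeps five state variables: the weight `w`,
pre- and postsynaptic spike traces `x`, `y`, an eligibility trace `c` and a
learning rate `gamma`.

* Traces decay with `tau_plus = tau_minus = 10` ms and jump by exactly 1 on
  their spike. The pair-based increment evaluated in a step is
  `A_minus * y` on a presynaptic spike plus `A_plus * x` on a postsynaptic
  spike (`A_plus = 1`, `A_minus = -1`), computed *after* the traces decay
  and *before* they jump, so a coincident pair contributes nothing. This
  recursion is exactly the all-pairs exponential-window sum, which the test
  suite verifies to 1e-9 against a brute-force oracle.
* The eligibility trace accumulates those increments and decays with
  `tau_c = 10` ms.
* Each reward channel keeps a scalar `r` that decays with `tau_r = 2` ms
  and jumps by `C_r = 0.07` whenever its dopaminergic unit releases.
* The weight then follows the improved rule
  `dw/dt = gamma(t) r(t) c(t) - (w - w0)/tau_w` (clamped at `w >= 0`), and
  the learning rate follows `dgamma/dt = l * r(t) c(t)` with `l = 3e-5`.

The decay term returns an exercised weight to its baseline `w0 = 1` once
reward ceases, so the *weights* hold no long-term memory; the *learning
rate* does, growing monotonically whenever reward and eligibility agree.
Under a constant reward-eligibility product `k` the weight settles at
`w0 + tau_w * gamma * k`, a fixed point the tests verify by brute-force
integration.

Two constants of this rule are not published and are therefore model-level
choices, exposed in the configuration:

* `tau_w = 1000` ms. The narrative of the course experiment has an
  exercised weight back at baseline a few seconds after its obstacle is
  passed, which is consistent with a time constant of about a second.
* `gamma0 = 1.2e-3`. The published account gives no initial learning rate,
  but it pins two behavioural facts: the first encounter's weight rise
  takes on the order of a second, and the per-trial learning-rate gain
  produced by `l` changes the decision time by several hundred
  milliseconds per trial. Both constrain `gamma0` through the same
  quantities (the reward-eligibility product the calibrated gate actually
  delivers, and the weight deviation at which the decision neuron reacts),
  and `gamma0 = 1.2e-3` places the first decision just late enough to fail
  and the learned ones early enough to succeed. With the naive choice
  `gamma0 = 1` the relative learning-rate growth per trial would be
  ~1e-4 and no trial-over-trial speedup could exist.

## The ten-neuron controller

The architecture has two mirror-symmetric channels plus a brake:

* **Left, Right** — integrator encoders driven by
  `I = gain * (I0 - C_i d)` with `I0 = 0.225` nA, `C_i = 0.005` nA/cm and
  readings clipped to `[15, 30]` cm. The table constants alone would give
  2.5–5 Hz through the integrator; a fixed encoder gain of 10 (equivalently
  a 10 MΩ encoder resistance) reconciles them with the stated operating
  points of 25 Hz at 30 cm and 50 Hz at 15 cm. The discrepancy is recorded,
  not hidden: the gain is a first-class, documented constant.
* **N1, N3** — pacemakers. A passive leaky unit cannot fire periodically
  without input, so each receives a constant bias current, set in closed
  form so the discrete-time period is exactly 40 ms (25 Hz).
* **N2, N4** — relays, driven solely by their pacemaker through the two
  plastic synapses (`w12`: N1→N2, `w34`: N3→N4) scaled by a calibrated
  relay drive gain.
* **Out** — the decision neuron, with N2 excitatory and N4 inhibitory at
  equal weights plus a closed-form bias.
* **Stop** — the brake, excited by both encoders.
* **R1, R2** — dopaminergic release units: leaky neurons whose threshold
  crossings emit reward releases instead of spikes. Each integrates the
  opposite-side sensor current (Left → R2, Right → R1) scaled by a gate
  drive gain, plus a synaptic pulse from its paired relay (N2 → R1,
  N4 → R2). Each channel's reward feeds only its own plastic synapse.

### How a decision happens

At baseline the two relays fire one spike per pacemaker period at identical
times, so their equally weighted pulses cancel exactly at Out, which fires
at its bias-driven 12 Hz. The relay drive gain is calibrated so that the
threshold for a *second* relay spike per period sits just above the
baseline weight: when reward drives `w34` up by roughly a percent, N4
doubles its per-period burst, the un-cancelled inhibitory pulses silence
Out, the 300 ms rate window drops below 8 Hz, and the robot turns right.
The mirrored path through `w12` locks Out to the burst rate (~25 Hz),
crosses the 18 Hz band and turns the robot left. Out's polarity follows the
functional contract (left obstacle ⇒ rate below the band ⇒ right turn),
which the published narrative states in both directions in different
places; the behavioural description of the course experiment (rising `w34`
⇒ falling Out rate ⇒ right turn) is taken as authoritative.

### Reward release

A release requires sensor drive near the 50 Hz end *and* concurrent relay
spikes — neither alone suffices. The gate drive gain is set in closed form
so the membrane plateau at `d_min` is 28.5 mV (1.5 mV below threshold); the
relay pulse weight is then found by bisection between the smallest weight
that produces releases at `d_min` within 200 ms and the largest that stays
silent at `d_max`, and placed in the upper quarter of that window so that
each relay spike near an obstacle triggers a short burst of releases. The
silence bound is verified both at the baseline weight and in the
doubled-relay regime; without the second check, a weight above the doubling
threshold would let reward regenerate itself at full range and the weight
would never relax (a bistability the calibration explicitly excludes).

### The brake

The Stop weight is bisected so that one encoder at 50 Hz can never fire
Stop over 5 s while both together fire it within 500 ms. Because the two
encoders at equal distance are phase-synchronous, their pulses coincide and
the conjunction is sharp.

### Calibration summary

`calibrate_network()` computes, in order: the pacemaker bias (closed form),
the relay drive gain (bisection for the burst-doubling boundary, then a
refinement that maximises the separation between that boundary and the
weight at which relay spike *timing* first shifts on the grid, so the first
observable response to learning is always the correctly-signed burst
doubling), the Out bias (closed form), the gate pulse weight and the Stop
weight (bisections). Everything is deterministic, and `verify = TRUE`
re-simulates every setpoint and attaches the measured report; any missed
setpoint is an error naming it.

## The synthetic environment

The world is a deterministic 2D plane (cm) with axis-aligned rectangular
obstacles, a disc robot (radius 5 cm) under unicycle kinematics, and two
single-ray range sensors at ±30° (a 60° span) clipped to `[15, 30]` cm.
The control loop exchanges data every 100 ms: sense, simulate 1000 network
steps, decode the Out rate over a sliding window against the 8/18 Hz bands
(both boundaries inclusive for "straight"), act. A trial begins with a 1 s
settling interval (robot parked) so the rate window is full before the
first decision.

Design choices the published system leaves open:

* **Motion**: `forward_speed = 4` cm/s and `turn_rate = 1.5` rad/s for the
  learning trials. The real drivetrain is unpublished; these values are
  chosen so an obstacle first sensed at 30 cm admits both outcomes — a
  first, late-deciding trial that clips the obstacle and learned trials
  that clear it. The course scenario uses a gentler 2 cm/s and 0.5 rad/s so
  avoidance rotations stay near 50–60° and a forward zigzag is possible.
* **Rate window**: 300 ms, re-evaluated every control period. A 1000 ms
  window was considered and rejected: it delays a rate *fall* by ~3 control
  periods relative to a rate *rise* (old spikes must drain out of the
  window), which makes mirrored left/right decisions measurably asymmetric.
  At the controller's three operating rates (0 / ~12 / ~25 Hz) the coarser
  3.3 Hz resolution of the short window cannot cause spurious band exits.
* **Decision time**: the interval from a trial's first reward release to
  its first non-straight command — a quantity directly measurable in the
  log, standing in for the published "time for the weight to rise to its
  maximum", which is not well defined here because the weight maximum is
  reward-duration-dependent.
* **Trial protocol**: trials are separated by repositioning the robot and
  letting the network idle 5 s at full range; weights relax to `w0` by the
  decay term while the learning rates persist — exactly the architecture's
  division of labour between fast and slow memory.
* **Scenarios**: `single_left` places a carton with its bottom edge on the
  robot's track line, 35 cm ahead of the start, so a straight path collides
  and an early right turn clears; `single_right` is its exact reflection.
  `slalom5` chains four alternating cartons along the robot's actual
  learned zigzag, then a double carton whose two halves are staggered a few
  cm so that, on the slightly oblique final leg, both sensor rays cross the
  proximity threshold together and the brake conjunction fires before
  either steering channel can decide. Obstacle groups mark the two halves
  as one obstacle.

## What the tests do and do not show

The closed-loop runs are bit-reproducible, and the test suite exploits
that: an oracle driver composed of the exported single-step operations must
reproduce the fast network loop *bitwise*, mirrored open-loop stimulation
must swap the two channels' weight, learning-rate and reward trajectories
*bitwise*, and mirrored closed-loop trials must mirror sensors, channels
and path bitwise up to the first turn. One asymmetry is accepted and
documented rather than hidden: Out's elevation is detected at a slightly
smaller weight deviation than its suppression (a consequence of the
asymmetric 8/18 Hz bands around the 12 Hz operating point and of the
knife-edge readout that the exact 12 Hz baseline requires), so mirrored
trials issue their first turns up to ~1.5 s apart and full-trial
trajectories are mirror images only up to that offset.

The environment emulates none of the following features of real hardware:
ultrasonic beam width and specular dropout (a single ray per sensor),
sensor noise (available as an option, off by default), wheel slip,
drivetrain latency, or the fixed-point arithmetic of an embedded
implementation. Passing tests therefore demonstrate the learning dynamics
and the controller's closed-loop logic, not robustness to real-world
sensing.

## Numerical choices and degenerate inputs

* `dt = 0.1` ms: the encoder integrator has `tau = 1` ms, so a 1 ms clock
  would be too coarse; at 0.1 ms the drive bias is ~1%.
* All pure-decay updates use exact exponential factors; thresholds are
  tested after the full step; ties (`v == v_th` exactly) fire.
* Weights clamp at zero rather than flipping synapse polarity; no upper
  clamp is imposed because the decay term bounds the weight dynamically.
* The learning rate is unbounded by design (its growth is the long-term
  memory); experiment durations keep it finite.
* Reward is non-negative; there is no punishment channel.
* Degenerate configuration values (non-positive time constants, inverted
  bands, negative distances) are rejected at validation with every
  violation listed; non-finite inputs to the step functions are parameter
  errors.

## Problem sizes

The defaults keep every experiment at desk scale: a learning trial
simulates ≤ 12 s of network time (120 000 steps), the three-trial
experiment about 50 s including inter-trial relaxation, and the course run
about 150 s. Calibration runs a few hundred thousand steps of probe
simulations. All are single-core and deterministic.
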