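neurons:
  if_tau: 1.0
  if_R: 1.0
  lif_tau: 5.0
  lif_R: 1.0
  v_rest: 0.0
  v_th: 30.0
  t_ref: 2.0
synapse:
  tau_s: 10.0
  gain_A: 0.5
plasticity:
  A_plus: 1.0
  A_minus: -1.0
  tau_plus: 10.0
  tau_minus: 10.0
  tau_c: 10.0
  tau_w: 1000.0
  w0: 1.0
  l: 3.0e-05
  gamma0: 0.0012
reward:
  tau_r: 2.0
  C_r: 0.07
encoder:
  I0: 0.225
  C_i: 0.005
  d_min: 15.0
  d_max: 30.0
  gain: 10.0
bands:
  low_hz: 8.0
  high_hz: 18.0
rate_window: 300.0
control_period: 100.0
dt: 0.1
motion:
  forward_speed: 4.0
  turn_rate: 1.5
experiment:
  scenario: single_left
  trials: 3.0
  max_duration: 12.0
  inter_trial_ms: 5000.0
  settle_ms: 1000.0
  sensor_noise: 0.0
  seed: 1.0
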