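## Learning dynamics: traces, eligibility, reward, classic vs improved rule.

## drive the trace/eligibility machinery over gridded spike trains the same
## way the network loop does: decay, increment with pre-jump traces, jump
accumulate_stdp <- function(pre, post, p, t_max, dt = 0.1) {
  s <- plastic_synapse_state(p)
  total <- 0
  for (k in seq_len(round(t_max / dt))) {
    t <- k * dt
    pre_sp <- any(abs(pre - t) < dt / 2)
    post_sp <- any(abs(post - t) < dt / 2)
    s <- update_traces(p, s, FALSE, FALSE, dt)     # decay only
    total <- total + stdp_increment(p, s, pre_sp, post_sp)
    if (pre_sp) s$x <- s$x + 1
    if (post_sp) s$y <- s$y + 1
  }
  total
}

test_that("traces decay exponentially and jump by one per spike", {
  p <- plasticity_params()
  s <- plastic_synapse_state(p)
  s$x <- 1
  for (k in 1:100) s <- update_traces(p, s, FALSE, FALSE, 0.1)
  expect_equal(s$x, exp(-1), tolerance = 1e-12)
  s <- update_traces(p, s, TRUE, TRUE, 0.1)
  expect_equal(s$x, exp(-1) * exp(-0.01) + 1, tolerance = 1e-12)
  expect_equal(s$y, 1)
})

test_that("a single pre/post pair reproduces the exponential learning window", {
  p <- plasticity_params()
  expect_equal(accumulate_stdp(0.1, 10.1, p, 20), exp(-1), tolerance = 1e-9)
  expect_equal(accumulate_stdp(10.1, 0.1, p, 20), -exp(-1), tolerance = 1e-9)
  expect_identical(accumulate_stdp(numeric(0), numeric(0), p, 5), 0)
  ## coincident pair contributes nothing
  expect_identical(accumulate_stdp(5, 5, p, 10), 0)
})

test_that("trace recursion equals the all-pairs brute-force sum", {
  p <- plasticity_params()
  set.seed(42)
  for (rep in 1:20) {
    pre <- random_train(sample(5:50, 1), 500)
    post <- random_train(sample(5:50, 1), 500)
    expect_equal(accumulate_stdp(pre, post, p, 520),
                 brute_force_stdp(pre, post, p),
                 tolerance = 1e-9)
  }
})

test_that("brute-force oracle handles empty and single-pair inputs", {
  p <- plasticity_params()
  expect_identical(brute_force_stdp(numeric(0), c(1, 2), p), 0)
  expect_equal(brute_force_stdp(0, 10, p), exp(-1), tolerance = 1e-12)
})

test_that("eligibility trace integrates increments with tau_c decay", {
  p <- plasticity_params()
  s <- plastic_synapse_state(p)
  s <- update_eligibility(p, s, 1, 0.1)
  for (k in 1:100) s <- update_eligibility(p, s, 0, 0.1)
  expect_equal(s$c, exp(-1), tolerance = 1e-10)
  s2 <- update_eligibility(p, s, 1, 0.1)
  expect_equal(s2$c, exp(-1) * exp(-0.01) + 1, tolerance = 1e-10)
})

test_that("reward variable jumps by C_r per release and decays with tau_r", {
  rs <- reward_state()
  rs <- update_reward(rs, 1, 0.1, t = 0.1)
  expect_equal(rs$r, 0.07)
  for (k in 1:20) rs <- update_reward(rs, 0, 0.1)
  expect_equal(rs$r, 0.07 / exp(1), tolerance = 1e-10)
  rs3 <- update_reward(reward_state(), 3, 0.1)
  expect_equal(rs3$r, 0.21)
})

test_that("classic rule integrates gamma * r * c and is sign-faithful", {
  p <- plasticity_params(gamma0 = 0.5)
  s <- plastic_synapse_state(p)
  s$c <- 2
  for (k in 1:1000) s <- classic_rstdp_step(s, 0.3, 0.1)
  ## constant r*c = 0.6 over 100 ms: dw = gamma * 0.6 * 100
  expect_equal(s$w, p$w0 + 0.5 * 0.6 * 100, tolerance = 1e-9)
  s2 <- plastic_synapse_state(p)
  s2$c <- -1
  s2 <- classic_rstdp_step(s2, 0.5, 0.1)
  expect_lt(s2$w, p$w0)
  expect_identical(classic_rstdp_step(s2, 0, 0.1)$w, s2$w)
})

test_that("with no reward the weight relaxes to w0 and gamma is untouched", {
  p <- plasticity_params()
  s <- plastic_synapse_state(p)
  s$w <- 2
  prev <- abs(s$w - p$w0)
  for (k in 1:10000) {
    s <- improved_rule_step(p, s, 0, 0.1)
    d <- abs(s$w - p$w0)
    expect_lt(d, prev)
    prev <- d
  }
  ## after 1000 ms = one tau_w, the excess is within O(dt/tau_w) of 1/e
  expect_equal(s$w, 1 + exp(-1), tolerance = 1e-3)
  expect_identical(s$gamma, p$gamma0)
})

test_that("gamma is non-decreasing whenever r*c >= 0", {
  p <- plasticity_params()
  s <- plastic_synapse_state(p)
  set.seed(7)
  for (k in 1:2000) {
    s$c <- abs(s$c) + stats::runif(1)
    g_before <- s$gamma
    s <- improved_rule_step(p, s, stats::runif(1, 0, 0.1), 0.1)
    expect_gte(s$gamma, g_before)
  }
})

test_that("constant r*c drives w to the fixed point w0 + tau_w*gamma*r*c", {
  p <- plasticity_params(l = 0, gamma0 = 0.01)
  s <- plastic_synapse_state(p)
  k_rc <- 0.4
  for (step in 1:80000) {
    s$c <- k_rc          # hold the product r*c at k_rc with r = 1
    s <- improved_rule_step(p, s, 1, 0.1)
  }
  expect_equal(s$w, p$w0 + p$tau_w * 0.01 * k_rc, tolerance = 1e-3)
})

test_that("improved rule degenerates to the classic rule without decay and l", {
  p <- plasticity_params(tau_w = Inf, l = 0, gamma0 = 0.02)
  s_imp <- plastic_synapse_state(p)
  s_cla <- plastic_synapse_state(p)
  set.seed(13)
  r_seq <- stats::runif(500, 0, 0.2)
  c_seq <- stats::rnorm(500)
  for (k in 1:500) {
    s_imp$c <- c_seq[k]; s_cla$c <- c_seq[k]
    s_imp <- improved_rule_step(p, s_imp, r_seq[k], 0.1)
    s_cla <- classic_rstdp_step(s_cla, r_seq[k], 0.1)
  }
  ## identical dynamics up to the two rules' multiplication order
  expect_equal(s_imp$w, s_cla$w, tolerance = 1e-12)
})

test_that("weights are clamped at zero", {
  p <- plasticity_params(gamma0 = 100)
  s <- plastic_synapse_state(p)
  s$c <- -100
  s <- improved_rule_step(p, s, 1, 0.1)
  expect_identical(s$w, 0)
})
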