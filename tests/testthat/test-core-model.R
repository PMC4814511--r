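test_that("f1 returns the exact branch gains with saturation precedence", {
  cases <- list(
    list(x1 = 0, expect = 0),       # above threshold
    list(x1 = -39.999, expect = 0),
    list(x1 = -40, expect = 1),     # at threshold: engaged
    list(x1 = -100, expect = 1),
    list(x1 = -700, expect = 0.1),  # at saturation: saturated branch wins
    list(x1 = -800, expect = 0.1))
  for (cs in cases)
    expect_identical(eval_f1(cs$x1, T = -40, S = -700), cs$expect)
  expect_error(eval_f1(NaN, -40, -700), "blow-up")
  expect_error(eval_f1(0, T = -40, S = -40), "S < T")
})

test_that("one state step matches hand-evaluated update equations", {
  p <- bp_model_params()  # dt = 0.001
  s0 <- oscillator_state()

  # zero fixed point of the homogeneous update
  s <- advance_state(s0, p, bpd = 0, v0 = 0)
  expect_identical(c(s$x1, s$x2), c(0, 0))
  expect_identical(s$n, 1L)

  # drive terms only: x1 = g1*dt*bpd, x2 = g0*dt*bpd
  s <- advance_state(s0, p, bpd = 50, v0 = 0)
  expect_equal(s$x1, -0.925, tolerance = 1e-12)
  expect_equal(s$x2, -4.4025, tolerance = 1e-12)

  # below threshold the f1 = 1 gains apply: (-h1-h5), (-h0-h4)
  s0$x1 <- -50
  s <- advance_state(s0, p, bpd = 0, v0 = 0)
  expect_equal(s$x1, (1 + (-p$h1 - p$h5) * p$dt) * -50, tolerance = 1e-12)
  expect_equal(s$x2, (-p$h0 - p$h4) * p$dt * -50, tolerance = 1e-12)

  # vestibular input enters the second state only
  s <- advance_state(oscillator_state(), p, bpd = 0, v0 = 7)
  expect_identical(s$x1, 0)
  expect_equal(s$x2, p$gv * p$dt * 7, tolerance = 1e-12)

  expect_error(advance_state(oscillator_state(), p, bpd = Inf, v0 = 0),
               "non-finite")
})

test_that("simulated states match an independent naive loop to 1e-12", {
  p <- bp_model_params()
  n <- 10
  bpd <- seq(45, 54, length.out = n)
  v0 <- sin(seq_len(n))
  oracle <- naive_state_loop(p, c(0, 0), bpd, v0, p$T, n)

  # route 1: composing the exported single-step operations
  s <- oscillator_state()
  for (k in seq_len(n)) s <- advance_state(s, p, bpd[k], v0[k])
  expect_equal(c(s$x1, s$x2), oracle[n, ], tolerance = 1e-12)

  # route 2: the inlined simulator loop
  stim <- stimulus_set(bpd = bpd, v0 = v0, duration = n * p$dt, dt = p$dt)
  tr <- simulate_bp(p, stim, warmup = 0)
  expect_equal(unname(cbind(tr$x1, tr$x2)), unname(oracle), tolerance = 1e-12)
})

test_that("f2 is a zero-intercept quartic with a steeper rising branch", {
  p <- bp_model_params()
  expect_identical(eval_f2(0, "rising", p), 0)
  expect_identical(eval_f2(0, "falling", p), 0)

  p_lin <- bp_model_params(nl_rise = c(0, 2, 0, 0, 0))
  expect_identical(eval_f2(3, "rising", p_lin), 6)

  for (u in c(0.5, 10, 1500, 15000, 40000))
    expect_gt(eval_f2(u, "rising", p), eval_f2(u, "falling", p))

  expect_error(bp_model_params(nl_rise = c(1, 2, 0, 0, 0)), "zero constant")
  expect_error(bp_model_params(nl_rise = c(0, 2, 0)), "5 finite")
})

test_that("high-pass filter has DC gain 0, unit passband, 1/sqrt(2) at fc", {
  fc <- 0.1; dt <- 0.001
  # constant input held much longer than 1/(2 pi fc): output decays to 0
  st <- 0; y <- NA
  for (i in seq_len(30 / dt * fc * 10)) {  # 30/(2 pi fc) ~ 48 s at fc = 0.1
    out <- highpass_step(st, 1, fc, dt); st <- out$hp_state; y <- out$y
  }
  expect_lt(abs(y), 1e-3)

  expect_equal(measured_hp_gain(fc, fc, dt), 1 / sqrt(2), tolerance = 0.02)
  expect_equal(measured_hp_gain(100 * fc, fc, dt, n_cycles = 200), 1,
               tolerance = 0.02)
  expect_error(highpass_step(0, 1, fc = -1, dt = dt), "positive")
})

test_that("output chain combines x2p, Desired BP, and bias per the output equation", {
  p <- bp_model_params()
  s <- oscillator_state()  # x2 = x2_prev = 0 so the chain adds nothing
  expect_identical(step_output_chain(s, p, bpd = 0)$bp, 30)
  expect_identical(step_output_chain(s, p, bpd = 50)$bp, 75)
  s$x2p <- 100
  expect_identical(step_output_chain(s, p, bpd = 50)$bp, 80)
})

test_that("trace output satisfies the output equation pointwise", {
  tr <- quick_trace(duration = 12)
  p <- attr(tr, "params")
  recomputed <- (-p$h6) * tr$x2p + p$g2 * tr$bpd_in + p$bias
  expect_identical(tr$bp, recomputed)
})

test_that("runs are bitwise reproducible and blow-ups are reported with a step index", {
  p <- bp_model_params()
  tp <- make_threshold_process("stochastic", T0 = p$T, sd = 5)
  stim <- stimulus_set(bpd = 50, threshold = tp, duration = 10, dt = p$dt,
                       seed = 42)
  tr1 <- simulate_bp(p, stim)
  tr2 <- simulate_bp(p, stim)
  expect_identical(tr1, tr2)

  # without the threshold element the no-feedback system diverges
  p0 <- bp_model_params(T = -1e15, S = -2e15)
  stim0 <- stimulus_set(bpd = 50, duration = 30, dt = p0$dt)
  expect_error(simulate_bp(p0, stim0, warmup = 0), "blow-up at step")
})

test_that("parameter validation enforces the documented invariants", {
  expect_error(bp_model_params(S = -10, T = -40), "S < T")
  expect_error(bp_model_params(dt = 0.01), "dt")
  expect_error(bp_model_params(dt = 0), "dt")
  expect_error(bp_model_params(hp_fc = 0), "hp_fc")
  expect_error(read_params_config(overrides = list(zz = 1)), "unknown")
  p <- read_params_config(overrides = list(T = -100))
  expect_identical(p$T, -100)
})
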