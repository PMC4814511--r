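# Independent naive evaluation of the oscillator state update: explicit
# matrix-vector arithmetic per step, written without reference to the
# package's simulator internals.
naive_state_loop <- function(p, x0 = c(0, 0), bpd, v0, T_series, n_steps) {
  bpd <- rep_len(bpd, n_steps)
  v0 <- rep_len(v0, n_steps)
  T_series <- rep_len(T_series, n_steps)
  x <- matrix(NA_real_, n_steps, 2)
  cur <- x0
  for (k in seq_len(n_steps)) {
    f <- if (cur[1] <= p$S) 0.1 else if (cur[1] <= T_series[k]) 1 else 0
    A <- matrix(c(1 + (-p$h1 - p$h5 * f) * p$dt, -p$h2 * p$dt,
                  (-p$h0 - p$h4 * f) * p$dt, 1 - p$h3 * p$dt),
                2, 2, byrow = TRUE)
    cur <- as.numeric(A %*% cur) +
      c(p$g1 * p$dt * bpd[k], p$g0 * p$dt * bpd[k] + p$gv * p$dt * v0[k])
    x[k, ] <- cur
  }
  x
}

# steady-state amplitude ratio of the package high-pass at frequency f,
# measured by projecting the filter output onto the driving quadratures
measured_hp_gain <- function(f, fc, dt, n_cycles = 20) {
  n <- round(n_cycles / f / dt)
  t <- (seq_len(n) - 1) * dt
  u <- sin(2 * pi * f * t)
  st <- 0
  y <- numeric(n)
  for (i in seq_len(n)) {
    out <- highpass_step(st, u[i], fc, dt)
    st <- out$hp_state
    y[i] <- out$y
  }
  keep <- t > n_cycles / f / 2  # discard transient
  ys <- y[keep]; ts <- t[keep]
  2 * sqrt(mean(ys * sin(2 * pi * f * ts))^2 +
           mean(ys * cos(2 * pi * f * ts))^2)
}

default_fs <- function(p) 1 / p$dt

quick_trace <- function(duration = 20, warmup = 5, bpd = 50, ...) {
  p <- bp_model_params(...)
  stim <- stimulus_set(bpd = bpd, duration = duration, dt = p$dt)
  simulate_bp(p, stim, warmup = warmup)
}
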