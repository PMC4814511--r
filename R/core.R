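#' Threshold/saturation element of the baroreflex feedback
#'
#' Piecewise-constant branch gain applied to the feedback terms of the
#' oscillator core.  Above the threshold `T` the extra feedback is off (0);
#' at or below `T` it is fully engaged (1), which makes the core under-damped
#' and triggers a systole; at or below the saturation `S` the gain collapses
#' to 0.1, limiting the excursion of the first state and with it the pulse
#' pressure.  The saturation branch takes precedence over the threshold
#' branch (`S < T`).
#'
#' @param x1 First oscillator state value.
#' @param T Threshold (x1 units).
#' @param S Saturation level (x1 units), `S < T`.
#' @return One of 0, 1, 0.1.
#' @examples
#' eval_f1(0, T = -40, S = -700)     # 0
#' eval_f1(-100, T = -40, S = -700)  # 1
#' eval_f1(-800, T = -40, S = -700)  # 0.1
#' @export
eval_f1 <- function(x1, T, S) {
  if (S >= T) stop("eval_f1: requires S < T", call. = FALSE)
  if (!is.finite(x1))
    stop("eval_f1: non-finite x1 (numerical blow-up of the run)",
         call. = FALSE)
  if (x1 <= S) return(0.1)
  if (x1 <= T) return(1)
  0
}

#' Two-branch quartic enhancement of the x2 derivative
#'
#' The output nonlinearity applied to the derivative of the second state.
#' A degree-4 polynomial with zero constant term, with separate coefficient
#' sets for the rising and falling edge of the derivative; the rising branch
#' has the greater slope, which sharpens the systolic upstroke relative to
#' the decline (a hysteresis in the derivative enhancement).
#'
#' @param u Derivative of x2 (per-step difference divided by `dt`).
#' @param branch `"rising"` or `"falling"`.
#' @param p A [bp_model_params()] object supplying `nl_rise` / `nl_fall`.
#' @return The enhanced derivative value.
#' @examples
#' p <- bp_model_params()
#' eval_f2(0, "rising", p)   # exactly 0
#' @export
eval_f2 <- function(u, branch = c("rising", "falling"), p) {
  branch <- match.arg(branch)
  if (!is.finite(u)) stop("eval_f2: non-finite input", call. = FALSE)
  co <- if (branch == "rising") p$nl_rise else p$nl_fall
  if (length(co) != 5L)
    stop("eval_f2: coefficient vector must have length 5", call. = FALSE)
  co[1] + u * (co[2] + u * (co[3] + u * (co[4] + u * co[5])))
}

# Bilinear-transform coefficients of the first-order high-pass
# H(s) = s / (s + 2*pi*fc): y[n] = b0 u[n] + b1 u[n-1] - a1 y[n-1],
# realized in transposed direct form II with a single state w.
hp_coefs <- function(fc, dt) {
  K <- 2 / dt
  wc <- 2 * pi * fc
  list(b0 = K / (K + wc), b1 = -K / (K + wc), a1 = (wc - K) / (wc + K))
}

#' One step of the first-order high-pass filter
#'
#' First-order high-pass with -3 dB frequency `fc`, discretized by the
#' bilinear transform: DC gain 0, high-frequency gain 1.  The filter state is
#' a single number (transposed direct-form II).
#'
#' @param hp_state Filter state carried between steps (0 at rest).
#' @param u Input sample.
#' @param fc Cut-in (-3 dB) frequency, Hz.
#' @param dt Sample interval, s.
#' @return A list with `hp_state` (updated) and `y` (filtered sample).
#' @examples
#' st <- 0
#' out <- highpass_step(st, 1, fc = 0.1, dt = 0.001)
#' out$y   # close to 1 for the first sample of a step input
#' @export
highpass_step <- function(hp_state, u, fc, dt) {
  if (fc <= 0 || dt <= 0) stop("highpass_step: fc and dt must be positive",
                               call. = FALSE)
  if (!is.finite(u)) stop("highpass_step: non-finite input", call. = FALSE)
  co <- hp_coefs(fc, dt)
  y <- co$b0 * u + hp_state
  list(hp_state = co$b1 * u - co$a1 * y, y = y)
}

#' Initial state of the oscillator and output chain
#'
#' The documented starting point of every simulation: both oscillator states,
#' the filter state, and the post-filter integrator all at zero, falling
#' branch, step index 0.
#'
#' @return An object of class `oscillator_state`.
#' @export
oscillator_state <- function() {
  structure(list(x1 = 0, x2 = 0, x2_prev = 0, dx2_prev = 0,
                 hp_state = 0, x2p = 0, branch = "falling", n = 0L),
            class = "oscillator_state")
}

#' @export
print.oscillator_state <- function(x, ...) {
  cat(sprintf("oscillator_state n=%d x1=%.6g x2=%.6g x2p=%.6g branch=%s\n",
              x$n, x$x1, x$x2, x$x2p, x$branch))
  invisible(x)
}

#' Advance the oscillator core by one step
#'
#' The discrete-time state update of the relaxation oscillator.  With
#' `f = eval_f1(x1, T_now, S)` evaluated once on the incoming x1 and used in
#' both state equations:
#'
#' \deqn{x_1(n+1) = [1 + (-h_1 - h_5 f)\Delta t]\, x_1(n) - h_2 \Delta t\, x_2(n) + g_1 \Delta t\, BP_d}
#' \deqn{x_2(n+1) = (-h_0 - h_4 f)\Delta t\, x_1(n) + (1 - h_3 \Delta t)\, x_2(n) + g_0 \Delta t\, BP_d + g_v \Delta t\, V_0}
#'
#' @param state An `oscillator_state`.
#' @param p A `bp_model_params`.
#' @param bpd Desired-BP input value at this step (mmHg scale).
#' @param v0 Vestibular input value at this step (model units).
#' @param T_now Threshold value at this step (x1 units); defaults to `p$T`.
#' @return The next `oscillator_state` (with `x2_prev` holding the old x2 and
#'   `n` incremented by 1).
#' @export
advance_state <- function(state, p, bpd, v0 = 0, T_now = p$T) {
  if (!all(is.finite(c(bpd, v0, T_now))))
    stop("advance_state: non-finite input at step ", state$n, call. = FALSE)
  f <- eval_f1(state$x1, T_now, p$S)
  dt <- p$dt
  x1n <- (1 + (-p$h1 - p$h5 * f) * dt) * state$x1 +
    (-p$h2 * dt) * state$x2 + p$g1 * dt * bpd
  x2n <- (-p$h0 - p$h4 * f) * dt * state$x1 +
    (1 - p$h3 * dt) * state$x2 + p$g0 * dt * bpd + p$gv * dt * v0
  if (!is.finite(x1n) || !is.finite(x2n))
    stop("advance_state: state became non-finite at step ", state$n + 1L,
         " (x1=", format(state$x1), ", x2=", format(state$x2), ")",
         call. = FALSE)
  state$x2_prev <- state$x2
  state$x1 <- x1n
  state$x2 <- x2n
  state$n <- state$n + 1L
  state
}

#' Advance the output chain by one step and emit a BP sample
#'
#' Computes the derivative of x2 from the state (`(x2 - x2_prev)/dt`),
#' updates the hysteresis branch (rising while the derivative is increasing,
#' falling otherwise), applies the two-branch quartic [eval_f2()], the
#' first-order high-pass [highpass_step()], and an explicit integrator
#' (`x2p <- x2p + dt * filtered`), and returns the BP output sample
#'
#' \deqn{z_2 = (-h_6)\, x_{2p} + g_2\, BP_d + Bias}
#'
#' @param state An `oscillator_state` whose `x2`/`x2_prev` reflect the most
#'   recent [advance_state()] call.
#' @param p A `bp_model_params`.
#' @param bpd Desired-BP value used in the output combination.
#' @return A list with `state` (updated `dx2_prev`, `branch`, `hp_state`,
#'   `x2p`) and `bp` (the output sample, mmHg scale), plus `dx2`.
#' @export
step_output_chain <- function(state, p, bpd) {
  dx2 <- (state$x2 - state$x2_prev) / p$dt
  state$branch <- if (dx2 > state$dx2_prev) "rising" else "falling"
  state$dx2_prev <- dx2
  fu <- eval_f2(dx2, state$branch, p)
  hp <- highpass_step(state$hp_state, fu, p$hp_fc, p$dt)
  state$hp_state <- hp$hp_state
  state$x2p <- state$x2p + p$dt * hp$y
  bp <- (-p$h6) * state$x2p + p$g2 * bpd + p$bias
  list(state = state, bp = bp, dx2 = dx2)
}
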