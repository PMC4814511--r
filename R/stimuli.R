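#' Piecewise-constant Desired-BP profile with linear ramps
#'
#' Builds a per-step Desired-BP series: `base` everywhere except inside the
#' given segments, with linear ramps of width `ramp` seconds at every
#' transition (entering and leaving a segment).  `ramp = 0` gives an exact
#' step, left-continuous at the transition.
#'
#' @param base Baseline Desired BP (mmHg scale).
#' @param segments List of `c(start, end, level)` triples in seconds/mmHg;
#'   segments must not overlap and must lie inside the run.
#' @param ramp Ramp width in seconds at each transition.
#' @param duration Run duration, s.
#' @param dt Step, s.
#' @return Numeric vector of length `round(duration/dt)`.
#' @examples
#' bpd <- make_bpd_profile(50, list(c(100, 200, 40)), ramp = 1,
#'                         duration = 300, dt = 0.01)
#' @export
make_bpd_profile <- function(base, segments = list(), ramp = 0,
                             duration, dt) {
  n <- round(duration / dt)
  t <- (seq_len(n) - 1) * dt
  out <- rep(base, n)
  if (length(segments)) {
    segs <- do.call(rbind, lapply(segments, function(s) {
      if (length(s) != 3) stop("each segment must be (start, end, level)",
                               call. = FALSE)
      s
    }))
    segs <- segs[order(segs[, 1]), , drop = FALSE]
    if (any(segs[, 1] >= segs[, 2]))
      stop("segment start must precede end", call. = FALSE)
    if (nrow(segs) > 1 &&
        any(segs[-1, 1] < segs[-nrow(segs), 2] + ramp))
      stop("overlapping segments (including ramps)", call. = FALSE)
    if (any(segs[, 2] > duration))
      stop("segment extends beyond run duration", call. = FALSE)
    for (i in seq_len(nrow(segs))) {
      s0 <- segs[i, 1]; s1 <- segs[i, 2]; lev <- segs[i, 3]
      inside <- t > s0 & t <= s1
      out[inside] <- lev
      if (ramp > 0) {
        up <- t > s0 & t <= s0 + ramp
        out[up] <- base + (lev - base) * (t[up] - s0) / ramp
        dn <- t > s1 & t <= s1 + ramp
        out[dn] <- lev + (base - lev) * (t[dn] - s1) / ramp
      }
    }
  }
  out
}

#' Sinusoidal galvanic vestibular stimulation waveform
#'
#' The central otolithic signal assumed to drive the baroreflex feedback
#' during sGVS: a fundamental plus a second harmonic,
#' `a1*sin(2*pi*f*t + phi1) + a2*sin(4*pi*f*t + phi2)` between `onset`
#' (inclusive) and `offset` (exclusive), zero elsewhere.  Low-frequency
#' stimulation (0.025 or 0.05 Hz) with a strong second harmonic is the
#' waveform used to evoke vasovagal oscillations.
#'
#' @param f Fundamental frequency, Hz.
#' @param a1,a2 Amplitudes of fundamental and second harmonic (model units).
#' @param phi1,phi2 Phases, rad.
#' @param onset,offset Stimulus window, s.
#' @param duration Run duration, s.
#' @param dt Step, s.
#' @return Numeric vector of length `round(duration/dt)`.
#' @export
make_sgvs_input <- function(f = 0.025, a1 = 3, a2 = 4.5,
                            phi1 = 0, phi2 = 0,
                            onset = 0, offset = Inf, duration, dt) {
  if (f <= 0) stop("f must be positive", call. = FALSE)
  if (a1 < 0 || a2 < 0) stop("amplitudes must be non-negative", call. = FALSE)
  if (onset >= offset) stop("onset must precede offset", call. = FALSE)
  n <- round(duration / dt)
  t <- (seq_len(n) - 1) * dt
  v <- a1 * sin(2 * pi * f * t + phi1) + a2 * sin(4 * pi * f * t + phi2)
  v[t < onset | t >= offset] <- 0
  v
}

#' Trapezoidal vestibular input modelling a static head-up tilt
#'
#' Zero before `onset`, linear rise over `rise` seconds to `amplitude`, held
#' until `offset`, then a linear return over `rise` seconds: the sustained
#' otolith signal of a nose-up tilt, a slower transient than sGVS.
#'
#' @param amplitude Plateau level (model units).
#' @param onset Start of the rise, s.
#' @param rise Ramp duration, s (> 0).
#' @param offset Start of the return ramp, s.
#' @param duration Run duration, s.
#' @param dt Step, s.
#' @return Numeric vector of length `round(duration/dt)`.
#' @export
make_tilt_input <- function(amplitude, onset, rise, offset, duration, dt) {
  if (rise <= 0) stop("rise must be positive", call. = FALSE)
  n <- round(duration / dt)
  t <- (seq_len(n) - 1) * dt
  v <- numeric(n)
  up <- t >= onset & t < onset + rise
  v[up] <- amplitude * (t[up] - onset) / rise
  hold <- t >= onset + rise & t < offset
  v[hold] <- amplitude
  dn <- t >= offset & t < offset + rise
  v[dn] <- amplitude * (1 - (t[dn] - offset) / rise)
  v
}

#' Threshold process driving the baroreflex feedback element
#'
#' Describes how the threshold `T` evolves over a run.  Three modes:
#' `constant` (T0 everywhere), `step` (T0 except `level` inside
#' `(start, end)`), and `stochastic` (base T0 plus an independent zero-mean
#' Gaussian perturbation of standard deviation `sd`, redrawn once per beat —
#' at each upward threshold recrossing that ends a beat's triggered phase —
#' and held until the next beat).  The stochastic realization therefore
#' happens inside [simulate_bp()], which logs the applied series; with
#' `sd = 0` it coincides with `constant` mode.
#'
#' @param mode `"constant"`, `"step"` or `"stochastic"`.
#' @param T0 Base threshold (x1 units).
#' @param step_spec `c(start, end, level)` for `step` mode (s, s, x1 units).
#' @param sd Standard deviation of the per-beat Gaussian jitter
#'   (`stochastic` mode), x1 units; must be >= 0.
#' @return An object of class `threshold_process`.
#' @examples
#' make_threshold_process("step", T0 = -40, step_spec = c(100, 200, -100))
#' @export
make_threshold_process <- function(mode = c("constant", "step", "stochastic"),
                                   T0 = -40, step_spec = NULL, sd = 5) {
  mode <- match.arg(mode)
  if (mode == "step") {
    if (is.null(step_spec) || length(step_spec) != 3)
      stop("step mode requires step_spec = c(start, end, level)",
           call. = FALSE)
    if (step_spec[1] >= step_spec[2])
      stop("step window start must precede end", call. = FALSE)
  }
  if (mode == "stochastic" && sd < 0)
    stop("sd must be non-negative", call. = FALSE)
  structure(list(mode = mode, T0 = T0, step_spec = step_spec,
                 sd = if (mode == "stochastic") sd else 0),
            class = "threshold_process")
}

# Deterministic base series of a threshold process (jitter excluded).
threshold_base_series <- function(tp, duration, dt) {
  n <- round(duration / dt)
  t <- (seq_len(n) - 1) * dt
  out <- rep(tp$T0, n)
  if (tp$mode == "step") {
    s <- tp$step_spec
    out[t > s[1] & t <= s[2]] <- s[3]
  }
  out
}

#' Bundle of time-aligned input series for one simulation run
#'
#' Collects the Desired-BP series, the vestibular input series, and the
#' threshold process that drive one run.  Scalars are recycled to constant
#' series.  Regenerating a `stimulus_set` (and the simulation driven by it)
#' with the same seed yields identical series.
#'
#' @param bpd Desired-BP series (mmHg scale) or scalar.
#' @param v0 Vestibular input series (model units) or scalar.
#' @param threshold A [make_threshold_process()] object, or a scalar/series
#'   of threshold values (treated as a constant/prescribed process).
#' @param duration Run duration, s.
#' @param dt Step, s.
#' @param seed Integer seed for the stochastic threshold realization.
#' @param description Free-text label carried into run metadata.
#' @return An object of class `stimulus_set` with per-step `bpd` and `v0`
#'   series of identical length, the threshold process, and the seed.
#' @export
stimulus_set <- function(bpd = 50, v0 = 0, threshold = NULL,
                         duration, dt, seed = 1L,
                         description = "") {
  n <- round(duration / dt)
  expand <- function(x, nm) {
    if (length(x) == 1L) rep(as.numeric(x), n)
    else if (length(x) == n) as.numeric(x)
    else stop("'", nm, "' must be a scalar or have one value per step (",
              n, ")", call. = FALSE)
  }
  bpd <- expand(bpd, "bpd")
  v0 <- expand(v0, "v0")
  if (is.null(threshold)) {
    # resolved to the model's own T at simulation time
    threshold <- structure(list(mode = "model", T0 = NA_real_,
                                step_spec = NULL, sd = 0),
                           class = "threshold_process")
  }
  if (is.numeric(threshold)) {
    tseries <- expand(threshold, "threshold")
    tp <- structure(list(mode = "prescribed", T0 = tseries[1],
                         step_spec = NULL, sd = 0, series = tseries),
                    class = "threshold_process")
  } else if (inherits(threshold, "threshold_process")) {
    tp <- threshold
  } else stop("'threshold' must be numeric or a threshold_process",
              call. = FALSE)
  if (any(!is.finite(bpd)) || any(!is.finite(v0)))
    stop("stimulus series must be finite", call. = FALSE)
  structure(list(bpd = bpd, v0 = v0, threshold = tp,
                 duration = duration, dt = dt, n = n,
                 seed = as.integer(seed), description = description),
            class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf(
    "stimulus_set: %d steps (%.4g s at dt=%g), bpd [%.3g, %.3g], v0 [%.3g, %.3g], threshold mode '%s' (T0=%g, sd=%g), seed %d\n",
    x$n, x$duration, x$dt, min(x$bpd), max(x$bpd), min(x$v0), max(x$v0),
    x$threshold$mode, x$threshold$T0, x$threshold$sd, x$seed))
  invisible(x)
}
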