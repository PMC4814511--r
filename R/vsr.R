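#' Vestibulo-sympathetic response curve: modulation depth vs input amplitude
#'
#' For each vestibular input amplitude, simulates the oscillator under the
#' sGVS waveform (fundamental `f` plus second harmonic scaled by
#' `a2_ratio`), detects beats, interpolates the systolic and diastolic
#' envelopes onto a uniform grid, and measures their modulation at the
#' stimulus fundamental and second harmonic by harmonic projection.  The
#' curve rises linearly at low amplitude and saturates — the signature of
#' the vestibulo-sympathetic reflex.
#'
#' @param p A [bp_model_params()] object.
#' @param amplitudes Sorted non-negative fundamental amplitudes to test.
#' @param f Stimulus fundamental frequency, Hz.
#' @param a2_ratio Second-harmonic/fundamental amplitude ratio.
#' @param duration Run duration per amplitude, s (>= 5 stimulus periods
#'   after warmup is recommended).
#' @param warmup Discarded lead-in, s.
#' @param envelope_fs Resampling rate of the beat envelopes, Hz.
#' @return Data frame with one row per amplitude: `amplitude`, `sys_mod`
#'   and `dia_mod` (root-sum-square modulation depth over the first two
#'   stimulus harmonics of the systolic/diastolic envelope, mmHg), and the
#'   per-harmonic components `sys_a1`, `sys_a2`, `dia_a1`, `dia_a2`.
#' @export
vsr_curve <- function(p, amplitudes, f = 0.025, a2_ratio = 1.5,
                      duration = 200, warmup = 40, envelope_fs = 10) {
  if (is.unsorted(amplitudes) || any(amplitudes < 0))
    stop("amplitudes must be sorted and non-negative", call. = FALSE)
  rows <- lapply(amplitudes, function(a) {
    v0 <- make_sgvs_input(f = f, a1 = a, a2 = a2_ratio * a,
                          duration = duration, dt = p$dt)
    stim <- stimulus_set(bpd = 50, v0 = v0, duration = duration, dt = p$dt)
    tr <- simulate_bp(p, stim, warmup = warmup)
    fs <- 1 / p$dt
    beats <- detect_beats(tr$bp, fs, t0 = tr$t[1])
    env_amp <- function(tt, pp) {
      grid <- seq(min(tt), max(tt), by = 1 / envelope_fs)
      y <- stats::approx(tt, pp, grid)$y
      harmonic_amplitudes(y, envelope_fs, f, 2)
    }
    sa <- env_amp(beats$sys_t, beats$sys_p)
    da <- env_amp(beats$dia_t, beats$dia_p)
    data.frame(amplitude = a,
               sys_mod = sqrt(sum(sa^2)), dia_mod = sqrt(sum(da^2)),
               sys_a1 = sa[1], sys_a2 = sa[2],
               dia_a1 = da[1], dia_a2 = da[2])
  })
  do.call(rbind, rows)
}

#' Estimate the two-branch quartic f2 from paired derivative data
#'
#' Least-squares fit of two degree-4 polynomials with zero constant term on
#' the rising-edge and falling-edge subsets of paired samples (model
#' derivative vs target enhanced derivative), the procedure used to shape
#' the output nonlinearity against recorded pressure derivatives.  Edges are
#' classified by the change of the input derivative, matching the branch
#' rule of the simulator.
#'
#' @param dx2_model Model derivative series (regressor).
#' @param dbp_target Target enhanced-derivative series (response), aligned
#'   with `dx2_model`.
#' @return List with `nl_rise`, `nl_fall` (length-5 coefficient vectors,
#'   degree 0..4, constant term 0), and `rms_rise`, `rms_fall` residual RMS.
#' @export
fit_f2 <- function(dx2_model, dbp_target) {
  if (length(dx2_model) != length(dbp_target))
    stop("fit_f2: series must be aligned and equally long", call. = FALSE)
  rising <- c(FALSE, diff(dx2_model) > 0)
  fit_branch <- function(idx) {
    if (sum(idx) < 10)
      stop("fit_f2: a branch has fewer than 10 samples", call. = FALSE)
    u <- dx2_model[idx]; y <- dbp_target[idx]
    X <- cbind(u, u^2, u^3, u^4)
    cf <- stats::coef(stats::lm.fit(X, y))
    cf[is.na(cf)] <- 0
    res <- y - X %*% cf
    list(coef = c(0, unname(cf)), rms = sqrt(mean(res^2)))
  }
  up <- fit_branch(rising)
  dn <- fit_branch(!rising)
  list(nl_rise = up$coef, nl_fall = dn$coef,
       rms_rise = up$rms, rms_fall = dn$rms)
}

#' Multi-seed baroreflex-sensitivity experiment
#'
#' Repeats the stochastic-threshold sensitivity protocol over several seeds:
#' simulate with per-beat Gaussian threshold jitter and a given vestibular
#' input, detect beats, regress each R-R interval on the preceding systolic
#' pressure, and average the slope.  Single realizations are noisy; the mean
#' over seeds is the quantity compared across vestibular conditions.
#'
#' @param p A [bp_model_params()] object.
#' @param v0 `"none"`, `"constant"`, or `"sine"`; or a numeric per-step
#'   series.
#' @param v0_level Constant level or sine amplitude for the named modes.
#' @param v0_freq Sine frequency, Hz.
#' @param jitter_sd Per-beat threshold jitter SD, x1 units.
#' @param duration Run duration per seed, s.
#' @param warmup Discarded lead-in, s.
#' @param seeds Integer vector of seeds.
#' @param rr_units Units for R-R in the regression (see
#'   [baroreflex_sensitivity()]).
#' @return List with `slope_mean`, `slope_sd`, and `per_seed` (data frame of
#'   seed, slope, r, n_pairs).
#' @export
sensitivity_experiment <- function(p, v0 = c("none", "constant", "sine"),
                                   v0_level = 10, v0_freq = 0.025,
                                   jitter_sd = 5, duration = 60, warmup = 5,
                                   seeds = 1:10, rr_units = "ms") {
  n <- round(duration / p$dt)
  if (is.character(v0)) {
    v0 <- match.arg(v0)
    t <- (seq_len(n) - 1) * p$dt
    v0_series <- switch(v0,
      none = numeric(n),
      constant = rep(v0_level, n),
      sine = v0_level * sin(2 * pi * v0_freq * t))
  } else {
    v0_series <- v0
  }
  tp <- make_threshold_process("stochastic", T0 = p$T, sd = jitter_sd)
  rows <- lapply(seeds, function(s) {
    stim <- stimulus_set(bpd = 50, v0 = v0_series, threshold = tp,
                         duration = duration, dt = p$dt, seed = s)
    tr <- simulate_bp(p, stim, warmup = warmup)
    beats <- detect_beats(tr$bp, 1 / p$dt, t0 = tr$t[1])
    fit <- baroreflex_sensitivity(beats, rr_units = rr_units)
    data.frame(seed = s, slope = fit$slope, r = fit$r,
               n_pairs = fit$n_pairs)
  })
  per_seed <- do.call(rbind, rows)
  list(slope_mean = mean(per_seed$slope),
       slope_sd = stats::sd(per_seed$slope),
       per_seed = per_seed)
}
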