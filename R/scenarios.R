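#' Scenario presets reproducing the model's characteristic experiments
#'
#' @return Character vector of the available scenario names.
#' @export
scenario_names <- function() {
  c("baseline", "vvr_bpd_step", "threshold_step", "sgvs_oscillation",
    "tilt", "pp_vs_bpd_sweep", "vsr_amplitude_sweep",
    "sensitivity_v0_0", "sensitivity_v0_const", "sensitivity_v0_sin")
}

#' Specify a scenario run
#'
#' A named preset plus overrides.  Override keys may be any
#' [bp_model_params()] argument (e.g. `T`, `h2`, `dt`) or one of the
#' scenario-level keys `bpd`, `v0_level`, `jitter_sd`, `n_seeds`,
#' `amplitudes`, `bpd_levels`, `run_duration`; unknown keys are rejected.
#'
#' @param name One of [scenario_names()].
#' @param overrides Named list of overrides.
#' @param seed Integer master seed.
#' @param duration Optional run-duration override, s.
#' @param outputs Optional output directory for the result bundle.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, overrides = list(), seed = 1L,
                          duration = NULL, outputs = NULL) {
  if (!name %in% scenario_names())
    stop("unknown scenario '", name, "'; see scenario_names()", call. = FALSE)
  known <- c(names(formals(bp_model_params)),
             "bpd", "v0_level", "jitter_sd", "n_seeds", "amplitudes",
             "bpd_levels", "run_duration")
  bad <- setdiff(names(overrides), known)
  if (length(bad))
    stop("unknown override key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(name = name, overrides = overrides, seed = as.integer(seed),
                 duration = duration, outputs = outputs),
            class = "scenario_spec")
}

# windowed summaries of a trace interval
interval_metrics <- function(tr, fs, lo, hi, pp_window = 25) {
  sel <- tr$t >= lo & tr$t < hi
  beats <- detect_beats(tr$bp[sel], fs, t0 = min(tr$t[sel]))
  if (length(beats$sys_t) < 3)
    return(list(n_beats = length(beats$sys_t), mean_hr = NA_real_,
                mean_sys = NA_real_, mean_dia = NA_real_, mean_pp = NA_real_))
  pp <- pulse_pressure(beats, window = pp_window)
  list(n_beats = length(beats$sys_t),
       mean_hr = 1 / mean(beats$rr),
       mean_sys = mean(beats$sys_p),
       mean_dia = mean(beats$dia_p),
       mean_pp = mean(pp$windowed$pp))
}

#' Run a scenario preset end to end
#'
#' Composes stimulus generation, simulation, and analysis for the named
#' preset and returns a result bundle: the trace (where a single run is
#' involved), detected beats, and a metrics list that embeds the fully
#' resolved parameter set and seed so the bundle can be regenerated
#' identically.  With `spec$outputs` set, writes `trace.csv`, `beats.csv`,
#' and `metrics.json` there.
#'
#' Presets: `baseline` (constant drive, fixed-frequency oscillation);
#' `vvr_bpd_step` (Desired BP 50 to 40 at deep threshold: the anticompensatory
#' vaso-vagal pattern — systolic BP, HR and pulse pressure all fall);
#' `threshold_step` (threshold deepened at constant drive: HR falls but pulse
#' pressure rises — not a VVR); `sgvs_oscillation` (low-frequency vestibular
#' input with strong second harmonic modulating the systolic envelope);
#' `tilt` (trapezoidal sustained otolith input); `pp_vs_bpd_sweep` (pulse
#' pressure vs Desired BP: linear then saturating); `vsr_amplitude_sweep`
#' (modulation depth vs vestibular amplitude); and the three
#' `sensitivity_*` presets (stochastic threshold, multi-seed baroreflex
#' sensitivity with no / constant / sinusoidal vestibular input).
#'
#' @param spec A [scenario_spec()].
#' @return List with elements `name`, `trace` (or `NULL`), `beats` (or
#'   `NULL`), `table` (for sweep presets), and `metrics`.
#' @export
run_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  ov <- spec$overrides
  pk <- intersect(names(ov), names(formals(bp_model_params)))
  sk <- setdiff(names(ov), pk)
  p_base <- do.call(bp_model_params, ov[pk])
  sv <- function(key, default) if (key %in% sk) ov[[key]] else default
  seed <- spec$seed
  fs <- 1 / p_base$dt
  name <- spec$name
  trace <- NULL; beats <- NULL; tab <- NULL
  metrics <- list(scenario = name, seed = seed)

  if (name == "baseline") {
    dur <- if (!is.null(spec$duration)) spec$duration else 30
    stim <- stimulus_set(bpd = sv("bpd", 50), duration = dur, dt = p_base$dt,
                         seed = seed, description = "baseline")
    trace <- simulate_bp(p_base, stim, warmup = 5)
    beats <- detect_beats(trace$bp, fs, t0 = trace$t[1])
    pp <- pulse_pressure(beats)
    metrics <- c(metrics, list(
      n_beats = length(beats$sys_t),
      mean_hr = 1 / mean(beats$rr),
      hr_cv = stats::sd(beats$rr) / mean(beats$rr),
      mean_sys = mean(beats$sys_p), mean_dia = mean(beats$dia_p),
      mean_pp = mean(pp$per_beat$pp)))

  } else if (name == "vvr_bpd_step") {
    dur <- if (!is.null(spec$duration)) spec$duration else 200
    p <- if ("T" %in% pk) p_base else do.call(
      bp_model_params, c(ov[pk], list(T = -100)))
    bpd <- make_bpd_profile(sv("bpd", 50), list(c(dur / 2, dur, 40)),
                            ramp = 1, duration = dur, dt = p$dt)
    stim <- stimulus_set(bpd = bpd, duration = dur, dt = p$dt, seed = seed,
                         description = "Desired-BP step (VVR)")
    trace <- simulate_bp(p, stim, warmup = 5)
    beats <- detect_beats(trace$bp, fs, t0 = trace$t[1])
    pre <- interval_metrics(trace, fs, 5, dur / 2)
    post <- interval_metrics(trace, fs, dur / 2 + 5, dur)
    metrics <- c(metrics, list(
      hr_pre = pre$mean_hr, hr_post = post$mean_hr,
      sys_pre = pre$mean_sys, sys_post = post$mean_sys,
      pp_pre = pre$mean_pp, pp_post = post$mean_pp))

  } else if (name == "threshold_step") {
    dur <- if (!is.null(spec$duration)) spec$duration else 200
    tp <- make_threshold_process("step", T0 = p_base$T,
                                 step_spec = c(dur / 2, dur, -100))
    stim <- stimulus_set(bpd = sv("bpd", 50), threshold = tp, duration = dur,
                         dt = p_base$dt, seed = seed,
                         description = "threshold step")
    trace <- simulate_bp(p_base, stim, warmup = 5)
    beats <- detect_beats(trace$bp, fs, t0 = trace$t[1])
    pre <- interval_metrics(trace, fs, 5, dur / 2)
    post <- interval_metrics(trace, fs, dur / 2 + 5, dur)
    metrics <- c(metrics, list(
      hr_pre = pre$mean_hr, hr_post = post$mean_hr,
      sys_pre = pre$mean_sys, sys_post = post$mean_sys,
      pp_pre = pre$mean_pp, pp_post = post$mean_pp))

  } else if (name == "sgvs_oscillation") {
    dur <- if (!is.null(spec$duration)) spec$duration else 200
    a1 <- sv("v0_level", 3)
    v0 <- make_sgvs_input(f = 0.025, a1 = a1, a2 = 1.5 * a1,
                          duration = dur, dt = p_base$dt)
    stim <- stimulus_set(bpd = sv("bpd", 50), v0 = v0, duration = dur,
                         dt = p_base$dt, seed = seed, description = "sGVS")
    trace <- simulate_bp(p_base, stim, warmup = 40)
    beats <- detect_beats(trace$bp, fs, t0 = trace$t[1])
    grid <- seq(min(beats$sys_t), max(beats$sys_t), by = 0.1)
    env <- stats::approx(beats$sys_t, beats$sys_p, grid)$y
    ha <- harmonic_amplitudes(env, 10, 0.025, 2)
    metrics <- c(metrics, list(
      mean_hr = 1 / mean(beats$rr),
      sys_mod_fundamental = ha[1], sys_mod_second_harmonic = ha[2],
      second_harmonic_ratio = ha[2] / ha[1],
      vasovagal_band_power = band_power(env - mean(env), 10, 0.025, 0.05)))

  } else if (name == "tilt") {
    dur <- if (!is.null(spec$duration)) spec$duration else 200
    v0 <- make_tilt_input(amplitude = sv("v0_level", 3), onset = 60,
                          rise = 5, offset = 140, duration = dur,
                          dt = p_base$dt)
    stim <- stimulus_set(bpd = sv("bpd", 50), v0 = v0, duration = dur,
                         dt = p_base$dt, seed = seed, description = "tilt")
    trace <- simulate_bp(p_base, stim, warmup = 5)
    beats <- detect_beats(trace$bp, fs, t0 = trace$t[1])
    base <- interval_metrics(trace, fs, 5, 60)
    hold <- interval_metrics(trace, fs, 70, 140)
    metrics <- c(metrics, list(
      sys_baseline = base$mean_sys, sys_tilt = hold$mean_sys,
      hr_baseline = base$mean_hr, hr_tilt = hold$mean_hr,
      sys_shift = hold$mean_sys - base$mean_sys))

  } else if (name == "pp_vs_bpd_sweep") {
    levels <- sv("bpd_levels", seq(20, 150, by = 10))
    run_dur <- sv("run_duration", 40)
    p <- if ("T" %in% pk) p_base else do.call(
      bp_model_params, c(ov[pk], list(T = -100)))
    rows <- lapply(levels, function(b) {
      stim <- stimulus_set(bpd = b, duration = run_dur, dt = p$dt,
                           seed = seed)
      tr <- simulate_bp(p, stim, warmup = 5)
      bs <- detect_beats(tr$bp, fs, t0 = tr$t[1])
      pp <- pulse_pressure(bs)
      data.frame(bpd = b, mean_pp = mean(pp$per_beat$pp),
                 mean_hr = 1 / mean(bs$rr), mean_sys = mean(bs$sys_p))
    })
    tab <- do.call(rbind, rows)
    nlev <- nrow(tab)
    low <- seq_len(floor(0.8 * nlev))
    fit <- stats::lm(mean_pp ~ bpd, data = tab[low, ])
    top <- tab[tab$bpd >= stats::quantile(tab$bpd, 0.8), ]
    top_slope <- if (nrow(top) >= 2)
      unname(stats::coef(stats::lm(mean_pp ~ bpd, data = top))[2])
      else NA_real_
    metrics <- c(metrics, list(
      linear_slope = unname(stats::coef(fit)[2]),
      linear_r2 = summary(fit)$r.squared,
      top_quintile_slope = top_slope,
      saturation_ratio = top_slope / unname(stats::coef(fit)[2])))

  } else if (name == "vsr_amplitude_sweep") {
    amps <- sv("amplitudes", c(0, 1, 2, 4, 6, 8, 10, 14, 20))
    tab <- vsr_curve(p_base, amps)
    inc <- diff(tab$sys_mod)
    damp <- diff(tab$amplitude)
    metrics <- c(metrics, list(
      low_range_increasing = all(inc[seq_len(min(3, length(inc)))] > 0),
      first_gain = inc[1] / damp[1],
      last_gain = inc[length(inc)] / damp[length(damp)],
      saturating = (inc[length(inc)] / damp[length(damp)]) <
        (inc[1] / damp[1]),
      max_sys_mod = max(tab$sys_mod)))

  } else if (grepl("^sensitivity_", name)) {
    mode <- switch(name,
                   sensitivity_v0_0 = "none",
                   sensitivity_v0_const = "constant",
                   sensitivity_v0_sin = "sine")
    # both vestibular conditions use the printed input level V0 = 10
    lvl <- sv("v0_level", 10)
    n_seeds <- sv("n_seeds", 10)
    seeds <- seed * 1000L + seq_len(n_seeds)
    res <- sensitivity_experiment(
      p_base, v0 = mode, v0_level = lvl,
      jitter_sd = sv("jitter_sd", 5),
      duration = if (!is.null(spec$duration)) spec$duration else 60,
      seeds = seeds)
    tab <- res$per_seed
    metrics <- c(metrics, list(
      slope_mean = res$slope_mean, slope_sd = res$slope_sd,
      n_seeds = n_seeds, v0_mode = mode, v0_level = lvl))
  }

  metrics$params <- unclass(if (exists("p", inherits = FALSE)) p else p_base)
  out <- list(name = name, trace = trace, beats = beats, table = tab,
              metrics = metrics)
  if (!is.null(spec$outputs)) {
    dir.create(spec$outputs, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(trace))
      write_bp_trace(trace, file.path(spec$outputs, "trace.csv"))
    if (!is.null(beats))
      write_beats(beats, file.path(spec$outputs, "beats.csv"))
    if (!is.null(tab))
      utils::write.csv(tab, file.path(spec$outputs, "table.csv"),
                       row.names = FALSE)
    jsonlite::write_json(metrics, file.path(spec$outputs, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Evaluate metric expectations against a scenario's metrics
#'
#' Each expectation row names a metric and a comparison: `op` is one of
#' `gt`, `ge`, `lt`, `le` (sign/ordering constraints, compared against
#' `value`) or `within` (|observed - value| <= tol).  Metrics absent from
#' the metrics list are marked unevaluable (`pass = NA`), never silently
#' passed.
#'
#' @param metrics Named list (e.g. `run_scenario(...)$metrics`).
#' @param expectations Data frame with columns `metric`, `op`, `value`, and
#'   optionally `tol`.
#' @return Data frame with columns `metric`, `op`, `value`, `observed`,
#'   `pass`.
#' @export
compare_metrics <- function(metrics, expectations) {
  if (!nrow(expectations))
    return(data.frame(metric = character(0), op = character(0),
                      value = numeric(0), observed = numeric(0),
                      pass = logical(0)))
  rows <- lapply(seq_len(nrow(expectations)), function(i) {
    e <- expectations[i, ]
    obs <- metrics[[e$metric]]
    pass <- if (is.null(obs) || !is.numeric(obs)) NA else switch(
      as.character(e$op),
      gt = obs > e$value, ge = obs >= e$value,
      lt = obs < e$value, le = obs <= e$value,
      within = abs(obs - e$value) <=
        (if ("tol" %in% names(e) && !is.na(e$tol)) e$tol else 0),
      stop("unknown op '", e$op, "'", call. = FALSE))
    data.frame(metric = e$metric, op = e$op, value = e$value,
               observed = if (is.null(obs)) NA_real_ else as.numeric(obs),
               pass = pass)
  })
  do.call(rbind, rows)
}
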