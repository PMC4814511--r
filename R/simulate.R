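#' Simulate the blood-pressure relaxation oscillator
#'
#' Runs the discrete-time oscillator and its output chain from the documented
#' zero initial state for `duration/dt` steps under the inputs in `stim`,
#' discards the first `warmup` seconds, and returns the retained samples as a
#' `bp_trace` data frame with columns `t, x1, x2, dx2, x2p, bp, f1, bpd_in,
#' v_in, T_in`.
#'
#' The loop body is algebraically identical to composing [advance_state()]
#' and [step_output_chain()] (a property the test suite asserts); it is
#' inlined here so long runs stay fast.  A run with a stochastic threshold
#' process redraws the threshold jitter once per beat, at the upward
#' recrossing of the (jittered) threshold that ends the beat's triggered
#' phase; the realized threshold series is logged in `T_in`.  Identical
#' `(p, stim, seed)` give bitwise-identical traces.
#'
#' @param p A [bp_model_params()] object.
#' @param stim A [stimulus_set()]; its `duration`/`dt` must cover the run.
#' @param duration Simulated duration in seconds (defaults to the stimulus
#'   duration).
#' @param warmup Leading seconds discarded from the returned trace
#'   (default 5; the transient from the zero initial state).
#' @param seed Integer seed for the stochastic threshold realization;
#'   defaults to the seed carried by `stim`.
#' @return A `bp_trace` data frame; attributes carry the parameter set, the
#'   seed, `dt`, and the warmup.
#' @examples
#' p <- bp_model_params(dt = 0.001)
#' st <- stimulus_set(bpd = 50, duration = 12, dt = p$dt)
#' tr <- simulate_bp(p, st, warmup = 5)
#' range(tr$bp)
#' @export
simulate_bp <- function(p, stim, duration = stim$duration, warmup = 5,
                        seed = stim$seed) {
  stopifnot(inherits(p, "bp_model_params"), inherits(stim, "stimulus_set"))
  if (abs(stim$dt - p$dt) > 1e-12)
    stop("stimulus dt (", stim$dt, ") does not match model dt (", p$dt, ")",
         call. = FALSE)
  if (duration > stim$duration + 1e-9)
    stop("stimulus series do not cover the requested duration", call. = FALSE)
  if (warmup < 0 || warmup >= duration)
    stop("need duration > warmup >= 0", call. = FALSE)
  n <- round(duration / p$dt)
  dt <- p$dt
  tp <- stim$threshold
  Tbase <- if (tp$mode == "prescribed") tp$series[seq_len(n)]
           else if (tp$mode == "model") rep(p$T, n)
           else threshold_base_series(tp, duration, dt)
  jitter_sd <- tp$sd

  # RNG isolated so a simulation does not disturb the caller's stream
  runif(1)  # force .Random.seed to exist
  old_seed <- .Random.seed
  on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  co <- hp_coefs(p$hp_fc, dt)
  h0 <- p$h0; h1 <- p$h1; h2 <- p$h2; h3 <- p$h3; h4 <- p$h4; h5 <- p$h5
  g0 <- p$g0; g1 <- p$g1; gv <- p$gv; S <- p$S
  r1 <- p$nl_rise[2]; r2 <- p$nl_rise[3]; r3 <- p$nl_rise[4]; r4 <- p$nl_rise[5]
  f1c <- p$nl_fall[2]; f2c <- p$nl_fall[3]; f3c <- p$nl_fall[4]; f4c <- p$nl_fall[5]
  b0 <- co$b0; b1 <- co$b1; a1 <- co$a1
  out_gain <- -p$h6; g2 <- p$g2; bias <- p$bias

  x1 <- 0; x2 <- 0; dx2_prev <- 0; hp_state <- 0; x2p <- 0
  X1 <- numeric(n); X2 <- numeric(n); DX2 <- numeric(n)
  X2P <- numeric(n); BP <- numeric(n); F1 <- numeric(n); TIN <- numeric(n)
  bpd_in <- stim$bpd[seq_len(n)]
  v_in <- stim$v0[seq_len(n)]

  jit <- if (jitter_sd > 0) stats::rnorm(1, 0, jitter_sd) else 0
  triggered <- FALSE

  for (i in seq_len(n)) {
    T_now <- Tbase[i] + jit
    # per-beat jitter: redraw when x1 recrosses the threshold upward
    if (jitter_sd > 0) {
      if (!triggered && x1 <= T_now) {
        triggered <- TRUE
      } else if (triggered && x1 > T_now) {
        triggered <- FALSE
        jit <- stats::rnorm(1, 0, jitter_sd)
        T_now <- Tbase[i] + jit
      }
    }
    f <- if (x1 <= S) 0.1 else if (x1 <= T_now) 1 else 0
    bpd <- bpd_in[i]
    x1n <- (1 + (-h1 - h5 * f) * dt) * x1 + (-h2 * dt) * x2 + g1 * dt * bpd
    x2n <- (-h0 - h4 * f) * dt * x1 + (1 - h3 * dt) * x2 + g0 * dt * bpd +
      gv * dt * v_in[i]
    if (!is.finite(x1n) || !is.finite(x2n) || abs(x1n) > 1e12)
      stop("simulate_bp: numerical blow-up at step ", i, " (t=",
           format((i - 1) * dt), " s; x1=", format(x1), ", x2=", format(x2),
           ")", call. = FALSE)
    dx2 <- (x2n - x2) / dt
    rising <- dx2 > dx2_prev
    dx2_prev <- dx2
    x1 <- x1n; x2 <- x2n
    fu <- if (rising) dx2 * (r1 + dx2 * (r2 + dx2 * (r3 + dx2 * r4)))
          else dx2 * (f1c + dx2 * (f2c + dx2 * (f3c + dx2 * f4c)))
    y <- b0 * fu + hp_state
    hp_state <- b1 * fu - a1 * y
    x2p <- x2p + dt * y
    X1[i] <- x1; X2[i] <- x2; DX2[i] <- dx2; X2P[i] <- x2p
    BP[i] <- out_gain * x2p + g2 * bpd + bias
    F1[i] <- f; TIN[i] <- T_now
  }
  keep <- seq_len(n) > round(warmup / dt)
  tr <- data.frame(t = ((seq_len(n) - 1) * dt)[keep],
                   x1 = X1[keep], x2 = X2[keep], dx2 = DX2[keep],
                   x2p = X2P[keep], bp = BP[keep], f1 = F1[keep],
                   bpd_in = bpd_in[keep], v_in = v_in[keep], T_in = TIN[keep])
  attr(tr, "params") <- p
  attr(tr, "dt") <- dt
  attr(tr, "seed") <- as.integer(seed)
  attr(tr, "warmup") <- warmup
  attr(tr, "description") <- stim$description
  class(tr) <- c("bp_trace", "data.frame")
  tr
}

#' @export
print.bp_trace <- function(x, ...) {
  cat(sprintf(
    "bp_trace: %d samples at dt=%g s (t in [%.4g, %.4g] s), bp in [%.4g, %.4g] mmHg\n",
    nrow(x), attr(x, "dt"), min(x$t), max(x$t), min(x$bp), max(x$bp)))
  invisible(x)
}

#' Write a simulation trace to CSV with a JSON metadata sidecar
#'
#' One row per retained step with the trace columns; the sidecar
#' (`<path>.meta.json`) records the full resolved parameter set, the seed,
#' and the warmup, so the run can be regenerated bit-identically.
#'
#' @param trace A `bp_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_bp_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  p <- attr(trace, "params")
  meta <- list(params = unclass(p), dt = attr(trace, "dt"),
               seed = attr(trace, "seed"), warmup = attr(trace, "warmup"),
               description = attr(trace, "description"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a sampled BP trace from CSV
#'
#' Accepts raw pressure recordings: one column of mmHg values (header
#' optional), sampled at `fs` Hz.  A multi-column file (e.g. a written
#' `bp_trace`) is accepted when it has a `bp` column.
#'
#' @param path CSV path.
#' @param fs Sampling rate, Hz.
#' @return A data frame with columns `t` and `bp`.
#' @export
read_bp_csv <- function(path, fs) {
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  first <- utils::read.csv(path, header = FALSE, nrows = 1)
  has_header <- is.na(suppressWarnings(as.numeric(first[[1]][1])))
  d <- utils::read.csv(path, header = has_header)
  bp <- if ("bp" %in% names(d)) as.numeric(d$bp) else as.numeric(d[[1]])
  data.frame(t = (seq_along(bp) - 1) / fs, bp = bp)
}
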