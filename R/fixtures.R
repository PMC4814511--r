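#' Synthetic triangular BP trace with known beat times
#'
#' Emits an idealized arterial-pressure waveform — a fast linear systolic
#' upstroke followed by a slower linear decline to the diastolic level, the
#' approximately triangular beat shape of recorded pressure — with exactly
#' known systole/diastole times and pressures.  Used to validate the
#' beat-detection and rate/pressure operators against ground truth.
#'
#' @param n_beats Number of beats.
#' @param rr Inter-systolic interval, s; a vector of length `n_beats` gives
#'   per-beat intervals (e.g. to encode a known HR modulation).
#' @param sys_p Systolic level(s), mmHg (scalar or per beat).
#' @param dia_p Diastolic level(s), mmHg (scalar or per beat).
#' @param upstroke_frac Fraction of each beat spent on the upstroke.
#' @param fs Sampling rate, Hz.
#' @param noise_sd Gaussian measurement noise SD, mmHg.
#' @param seed Seed for the noise.
#' @return List with `t`, `bp`, and the ground truth `sys_t`, `sys_p`,
#'   `dia_t`, `dia_p` (beat apex/trough times as sampled).
#' @examples
#' fx <- synth_triangular_bp(n_beats = 5, rr = 0.25, fs = 1000)
#' @export
synth_triangular_bp <- function(n_beats, rr = 0.2, sys_p = 120, dia_p = 80,
                                upstroke_frac = 0.3, fs = 1000,
                                noise_sd = 0, seed = 1L) {
  stopifnot(n_beats >= 1, all(rr > 0), upstroke_frac > 0, upstroke_frac < 1)
  rr <- rep_len(rr, n_beats)
  sys_p <- rep_len(sys_p, n_beats)
  dia_p <- rep_len(dia_p, n_beats)
  onset <- c(0, cumsum(rr))[seq_len(n_beats)]   # beat starts (diastole)
  dur <- sum(rr)
  t <- seq(0, dur, by = 1 / fs)
  bp <- numeric(length(t))
  sys_t <- numeric(n_beats)
  for (k in seq_len(n_beats)) {
    t_up <- onset[k] + upstroke_frac * rr[k]
    seg <- t >= onset[k] & t < onset[k] + rr[k]
    tt <- t[seg]
    up <- tt < t_up
    y <- numeric(length(tt))
    y[up] <- dia_p[k] + (sys_p[k] - dia_p[k]) * (tt[up] - onset[k]) /
      (upstroke_frac * rr[k])
    dia_next <- dia_p[min(k + 1, n_beats)]
    y[!up] <- sys_p[k] + (dia_next - sys_p[k]) * (tt[!up] - t_up) /
      (rr[k] - upstroke_frac * rr[k])
    bp[seg] <- y
    sys_t[k] <- t[seg][which.max(y)]
  }
  bp[length(bp)] <- dia_p[n_beats]
  if (noise_sd > 0) {
    set.seed(seed)
    bp <- bp + stats::rnorm(length(bp), 0, noise_sd)
  }
  list(t = t, bp = bp, sys_t = sys_t, sys_p = sys_p,
       dia_t = onset, dia_p = dia_p)
}
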