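#' Detect systoles and diastoles in a sampled BP trace
#'
#' Systoles are local maxima with topographic prominence at least
#' `prominence` mmHg, separated by at least `min_rr` seconds (when two
#' candidates are closer, the higher one wins).  Each diastole is the
#' minimum between consecutive systoles.  A constant or empty series yields
#' an empty beat series, not an error.
#'
#' @param bp Numeric vector of pressure samples (mmHg).
#' @param fs Sampling rate, Hz.
#' @param min_rr Minimum inter-systolic interval, s.  The default 0.08 s
#'   suits rat heart rates (3-6 Hz).
#' @param prominence Minimum peak prominence, mmHg.
#' @param t0 Time of the first sample, s (so beat times can be reported on
#'   the clock of a trimmed trace).
#' @return An object of class `beat_series`: systole times/pressures
#'   (`sys_t`, `sys_p`), diastole times/pressures (`dia_t`, `dia_p`, one per
#'   inter-systolic gap), and `rr` (inter-systolic intervals, s).
#' @examples
#' tr <- synth_triangular_bp(n_beats = 10, rr = 0.2, fs = 500)
#' b <- detect_beats(tr$bp, fs = 500)
#' length(b$sys_t)
#' @export
detect_beats <- function(bp, fs, min_rr = 0.08, prominence = 2, t0 = 0) {
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  empty <- structure(list(sys_t = numeric(0), sys_p = numeric(0),
                          dia_t = numeric(0), dia_p = numeric(0),
                          rr = numeric(0)), class = "beat_series")
  n <- length(bp)
  if (n < 3 || !any(is.finite(bp)) || diff(range(bp)) == 0) return(empty)

  d <- diff(bp)
  # local maxima; treat plateau tops as a single peak at their left edge
  s <- sign(d)
  s_nz <- s
  for (i in seq_along(s_nz)) if (s_nz[i] == 0 && i > 1) s_nz[i] <- s_nz[i - 1]
  cand <- which(diff(s_nz) < 0) + 1L
  cand <- cand[cand > 1 & cand < n]
  if (!length(cand)) return(empty)

  prom <- vapply(cand, function(p) {
    h <- bp[p]
    l <- p - 1L
    lmin <- h
    while (l >= 1L && bp[l] <= h) { if (bp[l] < lmin) lmin <- bp[l]; l <- l - 1L }
    if (l < 1L) lmin <- min(bp[1:p])
    r <- p + 1L
    rmin <- h
    while (r <= n && bp[r] <= h) { if (bp[r] < rmin) rmin <- bp[r]; r <- r + 1L }
    if (r > n) rmin <- min(bp[p:n])
    h - max(lmin, rmin)
  }, numeric(1))
  cand <- cand[prom >= prominence]
  if (!length(cand)) return(empty)

  # enforce min_rr, highest peaks first
  min_sep <- min_rr * fs
  ord <- cand[order(bp[cand], decreasing = TRUE)]
  accepted <- integer(0)
  for (p in ord) {
    if (!length(accepted) || all(abs(accepted - p) >= min_sep))
      accepted <- c(accepted, p)
  }
  pk <- sort(accepted)

  sys_t <- t0 + (pk - 1) / fs
  sys_p <- bp[pk]
  dia_t <- dia_p <- numeric(0)
  if (length(pk) >= 2) {
    dia_idx <- vapply(seq_len(length(pk) - 1), function(k) {
      seg <- pk[k]:pk[k + 1]
      seg[which.min(bp[seg])]
    }, integer(1))
    dia_t <- t0 + (dia_idx - 1) / fs
    dia_p <- bp[dia_idx]
  }
  structure(list(sys_t = sys_t, sys_p = sys_p, dia_t = dia_t, dia_p = dia_p,
                 rr = diff(sys_t)),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("beat_series: %d systoles", length(x$sys_t)))
  if (length(x$rr))
    cat(sprintf(", mean RR %.4g s (HR %.4g Hz)", mean(x$rr), 1 / mean(x$rr)))
  cat("\n")
  invisible(x)
}

#' Write a beat series to CSV
#'
#' Columns `sys_t, sys_p, dia_t, dia_p, rr`; diastole and RR columns are one
#' entry shorter than the systole columns and are padded with NA.
#'
#' @param beats A `beat_series`.
#' @param path Output CSV path.
#' @export
write_beats <- function(beats, path) {
  ns <- length(beats$sys_t)
  pad <- function(v) c(v, rep(NA_real_, ns - length(v)))
  utils::write.csv(data.frame(sys_t = beats$sys_t, sys_p = beats$sys_p,
                              dia_t = pad(beats$dia_t),
                              dia_p = pad(beats$dia_p),
                              rr = pad(beats$rr)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Instantaneous heart rate from detected beats
#'
#' HR is the inverse of each inter-systolic interval, timestamped at the
#' closing systole.
#'
#' @param beats A `beat_series`.
#' @return Data frame with columns `t` (s) and `hr` (Hz); empty when fewer
#'   than 2 systoles were detected.
#' @export
heart_rate <- function(beats) {
  if (length(beats$sys_t) < 2)
    return(data.frame(t = numeric(0), hr = numeric(0)))
  data.frame(t = beats$sys_t[-1], hr = 1 / beats$rr)
}

#' Per-beat and windowed pulse pressure
#'
#' Pulse pressure of beat k is the systolic pressure minus the following
#' diastolic minimum.  The windowed series averages the per-beat values over
#' non-overlapping windows of `window` seconds (default 25 s, the interval
#' used when relating pulse pressure to slow BP modulations).
#'
#' @param beats A `beat_series`.
#' @param window Averaging window, s.
#' @return List with `per_beat` (data frame `t`, `pp`) and `windowed`
#'   (data frame `t` = window midpoints, `pp` = window means).
#' @export
pulse_pressure <- function(beats, window = 25) {
  ns <- length(beats$sys_t)
  if (ns < 2 || length(beats$dia_p) != ns - 1)
    stop("pulse_pressure: needs paired systole/diastole entries",
         call. = FALSE)
  pp <- beats$sys_p[-ns] - beats$dia_p
  tt <- beats$sys_t[-ns]
  bins <- floor((tt - tt[1]) / window)
  agg <- tapply(pp, bins, mean)
  mid <- tt[1] + (as.numeric(names(agg)) + 0.5) * window
  list(per_beat = data.frame(t = tt, pp = pp),
       windowed = data.frame(t = as.numeric(mid), pp = as.numeric(agg)))
}

#' Phase-plane trajectory of a BP trace
#'
#' Pairs each pressure sample with its time derivative (central differences,
#' optionally boxcar-smoothed), segments the trajectory into beat cycles
#' (systole to systole), and computes a cycle average by resampling every
#' cycle onto a common phase grid.  For a periodic trace the averaged
#' trajectory is closed: the gap between its first and last point is small
#' against the trajectory extent.
#'
#' @param bp Numeric pressure samples.
#' @param fs Sampling rate, Hz.
#' @param smoothing Boxcar width in samples applied to the derivative
#'   (0 or 1 = none).
#' @param n_phase Number of phase-grid points for the averaged cycle.
#' @param ... Passed to [detect_beats()].
#' @return List with `points` (data frame `bp`, `dbp`), `cycles` (list of
#'   per-cycle data frames), `avg_cycle` (data frame `phase`, `bp`, `dbp`),
#'   `closure` (relative start/end gap of the averaged cycle), and
#'   `dbp_peak_phase` (phase in `[0,1]`, measured from the preceding
#'   diastole, at which the averaged derivative peaks).
#' @export
phase_plane <- function(bp, fs, smoothing = 0, n_phase = 101, ...) {
  n <- length(bp)
  if (n < 3) stop("phase_plane: series too short", call. = FALSE)
  dbp <- c(bp[2] - bp[1], (bp[3:n] - bp[1:(n - 2)]) / 2,
           bp[n] - bp[n - 1]) * fs
  if (smoothing > 1) {
    k <- rep(1 / smoothing, smoothing)
    dbp <- stats::filter(dbp, k, sides = 2)
    dbp[is.na(dbp)] <- 0
    dbp <- as.numeric(dbp)
  }
  pts <- data.frame(bp = bp, dbp = dbp)
  if (diff(range(bp)) == 0)
    return(list(points = pts[1, , drop = FALSE], cycles = list(),
                avg_cycle = NULL, closure = 0, dbp_peak_phase = NA_real_))
  beats <- detect_beats(bp, fs, ...)
  # cycles bounded by diastoles so each cycle holds one full upstroke
  bounds <- round(beats$dia_t * fs) + 1L
  cycles <- list()
  if (length(bounds) >= 2) {
    for (k in seq_len(length(bounds) - 1)) {
      seg <- bounds[k]:bounds[k + 1]
      cycles[[k]] <- data.frame(bp = bp[seg], dbp = dbp[seg])
    }
  }
  avg <- NULL; closure <- NA_real_; peak_phase <- NA_real_
  if (length(cycles) >= 1) {
    grid <- seq(0, 1, length.out = n_phase)
    res <- function(cy, col) {
      ph <- seq(0, 1, length.out = nrow(cy))
      stats::approx(ph, cy[[col]], grid)$y
    }
    mbp <- rowMeans(vapply(cycles, res, numeric(n_phase), col = "bp"))
    mdb <- rowMeans(vapply(cycles, res, numeric(n_phase), col = "dbp"))
    avg <- data.frame(phase = grid, bp = mbp, dbp = mdb)
    ext <- sqrt(diff(range(mbp))^2 + diff(range(mdb))^2)
    gap <- sqrt((mbp[1] - mbp[n_phase])^2 + (mdb[1] - mdb[n_phase])^2)
    closure <- gap / ext
    peak_phase <- grid[which.max(mdb)]
  }
  list(points = pts, cycles = cycles, avg_cycle = avg, closure = closure,
       dbp_peak_phase = peak_phase)
}

#' Baroreflex sensitivity by the sequence method
#'
#' Ordinary least-squares fit of each R-R interval on the systolic pressure
#' of the beat that opens it (lag-0 pairing: the interval *following*
#' systole k is regressed on `sys_p[k]`).  A positive slope — higher
#' systolic pressure followed by a longer interval — is the compensatory
#' baroreflex pattern.
#'
#' @param beats A `beat_series` with at least 4 systoles (3 pairs).
#' @param rr_units `"ms"` (default) or `"s"` for the R-R intervals entering
#'   the regression.  Slopes are conventionally quoted in ms per mmHg.
#' @return An object of class `sensitivity_fit`: `slope`, `intercept`,
#'   `r` (Pearson correlation), `n_pairs`.
#' @export
baroreflex_sensitivity <- function(beats, rr_units = c("ms", "s")) {
  rr_units <- match.arg(rr_units)
  ns <- length(beats$sys_t)
  if (ns < 4)
    stop("baroreflex_sensitivity: needs at least 3 (pressure, interval) pairs",
         call. = FALSE)
  sp <- beats$sys_p[-ns]
  rr <- beats$rr * if (rr_units == "ms") 1000 else 1
  if (stats::sd(sp) == 0)
    stop("baroreflex_sensitivity: zero variance in systolic pressure",
         call. = FALSE)
  fit <- stats::lm(rr ~ sp)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = stats::cor(sp, rr), n_pairs = length(sp),
                 rr_units = rr_units),
            class = "sensitivity_fit")
}

#' @export
print.sensitivity_fit <- function(x, ...) {
  cat(sprintf(
    "baroreflex sensitivity: slope %.4g %s/mmHg (r = %.3f, n = %d)\n",
    x$slope, x$rr_units, x$r, x$n_pairs))
  invisible(x)
}

#' Power of a series in a frequency band
#'
#' Integrated one-sided periodogram over `[f_lo, f_hi]` after mean removal,
#' normalized so a pure tone of amplitude A contributes A^2/2.  The record
#' must span at least two periods of `f_lo` for the band to be resolvable.
#'
#' @param x Numeric series.
#' @param fs Sampling rate, Hz.
#' @param f_lo,f_hi Band edges, Hz (`0 < f_lo < f_hi`).
#' @return Band power (squared input units).
#' @examples
#' t <- seq(0, 400, by = 0.1)
#' band_power(3 * sin(2 * pi * 0.03 * t), fs = 10, 0.025, 0.05)  # ~ 4.5
#' @export
band_power <- function(x, fs, f_lo, f_hi) {
  if (f_lo <= 0 || f_hi <= f_lo) stop("need 0 < f_lo < f_hi", call. = FALSE)
  n <- length(x)
  if (n / fs < 2 / f_lo)
    stop("record shorter than 2 periods of f_lo: band unresolvable",
         call. = FALSE)
  x <- x - mean(x)
  X <- stats::fft(x)
  k <- seq_len(floor((n - 1) / 2))   # positive frequencies, ex DC/Nyquist
  f <- k * fs / n
  P <- 2 * Mod(X[k + 1])^2 / n^2
  sum(P[f >= f_lo & f <= f_hi])
}

#' Amplitudes of the harmonics of a known fundamental
#'
#' Projects the series onto sine/cosine pairs at `k * f0`,
#' `k = 1..k_max`, after truncating to an integer number of fundamental
#' periods, and returns the amplitude of each harmonic.
#'
#' @param x Numeric series.
#' @param fs Sampling rate, Hz.
#' @param f0 Fundamental frequency, Hz.
#' @param k_max Highest harmonic order; `k_max * f0` must lie below `fs/2`.
#' @return Numeric vector of length `k_max` of harmonic amplitudes.
#' @export
harmonic_amplitudes <- function(x, fs, f0, k_max = 2) {
  if (f0 <= 0 || k_max < 1) stop("need f0 > 0 and k_max >= 1", call. = FALSE)
  if (k_max * f0 >= fs / 2)
    stop("k_max * f0 reaches the Nyquist frequency: aliased", call. = FALSE)
  n <- length(x)
  n_per <- floor(n * f0 / fs)
  if (n_per < 1)
    stop("record shorter than one fundamental period", call. = FALSE)
  n_tr <- round(n_per * fs / f0)
  x <- x[seq_len(n_tr)]
  x <- x - mean(x)
  t <- (seq_len(n_tr) - 1) / fs
  vapply(seq_len(k_max), function(k) {
    w <- 2 * pi * k * f0 * t
    2 * sqrt(mean(x * sin(w))^2 + mean(x * cos(w))^2)
  }, numeric(1))
}
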