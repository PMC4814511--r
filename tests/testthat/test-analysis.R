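test_that("beat detection recovers known apices of synthetic triangular traces", {
  fs <- 1000
  fx <- synth_triangular_bp(n_beats = 10, rr = 0.2, fs = fs)
  b <- detect_beats(fx$bp, fs)
  expect_identical(length(b$sys_t), 10L)
  expect_true(all(abs(b$sys_t - fx$sys_t) <= 1 / fs + 1e-12))
  expect_identical(length(b$dia_t), 9L)
  expect_true(all(b$dia_t > b$sys_t[-10] & b$dia_t < b$sys_t[-1]))
  expect_true(all(b$rr > 0))

  # survives moderate measurement noise
  fxn <- synth_triangular_bp(n_beats = 10, rr = 0.2, fs = fs,
                             noise_sd = 0.5, seed = 2)
  bn <- detect_beats(fxn$bp, fs, prominence = 5)
  expect_identical(length(bn$sys_t), 10L)

  expect_identical(length(detect_beats(rep(80, 1000), fs)$sys_t), 0L)
  expect_identical(length(detect_beats(numeric(0), fs)$sys_t), 0L)

  single <- synth_triangular_bp(n_beats = 1, rr = 0.5, fs = fs)
  bs <- detect_beats(single$bp, fs)
  expect_identical(length(bs$sys_t), 1L)
  expect_identical(length(bs$dia_t), 0L)
})

test_that("heart rate is the inverse inter-systolic interval", {
  mk <- function(st) structure(
    list(sys_t = st, sys_p = rep(120, length(st)),
         dia_t = head(st, -1) + diff(st) / 2,
         dia_p = rep(80, length(st) - 1), rr = diff(st)),
    class = "beat_series")
  hr <- heart_rate(mk(c(0, 0.2, 0.4)))
  expect_equal(hr$hr, c(5, 5))
  expect_equal(hr$t, c(0.2, 0.4))
  hr2 <- heart_rate(mk(c(0, 0.2, 0.45)))
  expect_equal(hr2$hr, c(5, 4))
  expect_identical(nrow(heart_rate(mk(c(0)))), 0L)
})

test_that("pulse pressure: per-beat differences and windowed means", {
  fs <- 500
  fx <- synth_triangular_bp(n_beats = 40, rr = 0.5, sys_p = 120, dia_p = 80,
                            fs = fs)
  b <- detect_beats(fx$bp, fs)
  pp <- pulse_pressure(b, window = 5)
  expect_equal(pp$per_beat$pp, rep(40, nrow(pp$per_beat)), tolerance = 1e-6)
  expect_equal(pp$windowed$pp, rep(40, nrow(pp$windowed)), tolerance = 1e-6)

  # degenerate window: one beat per window reproduces the per-beat series
  pp1 <- pulse_pressure(b, window = 0.4)
  expect_equal(pp1$windowed$pp, pp1$per_beat$pp, tolerance = 1e-6)

  # rising systolic level: window means equal direct averages (hand oracle)
  sys_lv <- seq(100, 139, by = 1)
  fx2 <- synth_triangular_bp(n_beats = 40, rr = 0.5, sys_p = sys_lv,
                             dia_p = 80, fs = fs)
  b2 <- detect_beats(fx2$bp, fs)
  pp2 <- pulse_pressure(b2, window = 5)
  tt <- pp2$per_beat$t
  manual <- vapply(split(pp2$per_beat$pp, floor((tt - tt[1]) / 5)), mean,
                   numeric(1))
  expect_equal(pp2$windowed$pp, unname(manual))
})

test_that("phase plane: analytic sinusoid, degenerate input, closed cycles", {
  fs <- 1000
  t <- seq(0, 5, by = 1 / fs)
  A <- 2; f <- 3
  ph <- phase_plane(A * sin(2 * pi * f * t) + 100, fs)
  expect_equal(max(ph$points$dbp), 2 * pi * f * A, tolerance = 0.02)
  expect_equal(min(ph$points$dbp), -2 * pi * f * A, tolerance = 0.02)
  expect_lt(ph$closure, 0.05)

  phc <- phase_plane(rep(77, 100), fs)
  expect_identical(nrow(phc$points), 1L)
  expect_equal(phc$points$dbp, 0)
})

test_that("baroreflex sensitivity: exact line, null data, degenerate errors", {
  mk <- function(sp, rr_s) structure(
    list(sys_t = cumsum(c(0, rr_s)), sys_p = c(sp, sp[length(sp)]),
         dia_t = cumsum(c(0, rr_s))[-1] - rr_s / 2,
         dia_p = rep(80, length(rr_s)), rr = rr_s),
    class = "beat_series")

  sp <- c(100, 110, 120, 130, 125, 105)
  fit <- baroreflex_sensitivity(mk(sp, 0.5 * sp + 0.1), rr_units = "s")
  expect_equal(fit$slope, 0.5, tolerance = 1e-10)
  expect_equal(fit$r, 1, tolerance = 1e-10)
  expect_identical(fit$n_pairs, 6L)

  # independent pressure and interval: slope within 2 SE of zero
  set.seed(11)
  n <- 200
  sp <- 100 + rnorm(n, 0, 5)
  rr <- 0.2 + rnorm(n, 0, 0.01)
  fit0 <- baroreflex_sensitivity(mk(sp, rr), rr_units = "s")
  se <- sqrt(sum((rr - mean(rr))^2) / (n - 2)) /
    sqrt(sum((sp - mean(sp))^2)) # OLS slope SE, closed form
  expect_lt(abs(fit0$slope), 2 * se * 1.5)

  expect_error(baroreflex_sensitivity(mk(c(100, 110), c(0.2, 0.21))),
               "3 .*pairs")
  expect_error(baroreflex_sensitivity(mk(rep(100, 6), rep(0.2, 6))),
               "zero variance")
})

test_that("band power integrates a tone to A^2/2 and rejects out-of-band energy", {
  fs <- 10
  t <- seq(0, 800, by = 1 / fs)
  A <- 3
  x <- A * sin(2 * pi * 0.03 * t)
  expect_equal(band_power(x, fs, 0.025, 0.05), A^2 / 2, tolerance = 0.05)

  y <- A * sin(2 * pi * 0.2 * t)
  expect_lt(band_power(y, fs, 0.025, 0.05),
            0.01 * band_power(y, fs, 0.01, 4.9))

  expect_identical(band_power(numeric(8001), fs, 0.025, 0.05), 0)
  expect_error(band_power(x[1:100], fs, 0.025, 0.05), "unresolvable")
})

test_that("harmonic amplitudes recover constructed tones", {
  fs <- 10; f0 <- 0.025
  t <- seq(0, 400 - 1 / fs, by = 1 / fs)
  x <- 3 * sin(2 * pi * f0 * t) + 1.5 * sin(4 * pi * f0 * t + 0.7)
  a <- harmonic_amplitudes(x, fs, f0, 2)
  expect_equal(a, c(3, 1.5), tolerance = 0.01)

  pure <- 3 * sin(2 * pi * f0 * t)
  ap <- harmonic_amplitudes(pure, fs, f0, 2)
  expect_lt(ap[2], 0.01 * ap[1])

  expect_equal(harmonic_amplitudes(numeric(4000), fs, f0, 2), c(0, 0))
  expect_error(harmonic_amplitudes(x, fs, f0 = 3, k_max = 2), "Nyquist")
})

test_that("f2 fitting recovers known branch coefficients and noise floors", {
  set.seed(5)
  u <- as.numeric(stats::filter(rnorm(4000), rep(0.2, 5), circular = TRUE))
  rising <- c(FALSE, diff(u) > 0)
  cr <- c(0, 2.0, 0, 3e-2, 0); cf <- c(0, 1.2, 0, 1e-2, 0)
  evalp <- function(co, u) co[2] * u + co[3] * u^2 + co[4] * u^3 + co[5] * u^4
  target <- ifelse(rising, evalp(cr, u), evalp(cf, u))

  fit <- fit_f2(u, target)
  expect_equal(fit$nl_rise[c(2, 4)], cr[c(2, 4)], tolerance = 1e-6)
  expect_equal(fit$nl_fall[c(2, 4)], cf[c(2, 4)], tolerance = 1e-6)
  expect_lt(fit$rms_rise, 1e-8)

  # identity target: linear coefficient ~1, higher orders ~0
  fid <- fit_f2(u, u)
  expect_equal(fid$nl_rise[2], 1, tolerance = 1e-8)
  expect_lt(max(abs(fid$nl_rise[3:5])), 1e-6)

  # additive noise appears as the residual RMS
  sigma <- 0.3
  fitn <- fit_f2(u, target + rnorm(length(u), 0, sigma))
  expect_equal(fitn$rms_rise, sigma, tolerance = 0.2)
  expect_equal(fitn$rms_fall, sigma, tolerance = 0.2)

  expect_error(fit_f2(u[1:5], target[1:5]), "fewer than 10")
  expect_error(fit_f2(u, target[-1]), "aligned")
})
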