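#' Model parameters for the blood-pressure relaxation oscillator
#'
#' Constructs and validates the full parameter set of the oscillator: the
#' feedback gains of the two-state core, the threshold/saturation element in
#' the baroreflex feedback path, the Desired-BP feedforward gains, the
#' vestibular coupling gain, and the output chain (two-branch quartic
#' derivative enhancement, first-order high-pass filter, integrator, output
#' gains and bias).
#'
#' Defaults are the published parameter set of the model, with two
#' calibrations documented in the package vignette: the sign of `h2` is
#' corrected (the value as printed leaves the above-threshold subsystem with
#' a stable focus at positive x1, so the oscillation can never start; with
#' `h2 = -35.6` the above-threshold dynamics are non-oscillatory and drive x1
#' down across the threshold, and the below-threshold dynamics are
#' under-damped, exactly as the model is described), and the vestibular gain
#' `gv` is set equal to `g0` so that a unit of vestibular input is equipotent
#' with a unit of Desired BP.
#'
#' @param h0,h1,h2,h3,h4,h5 Feedback gains of the two-state oscillator core
#'   (model units).  `h5` and `h4` are engaged by the threshold element `f1`.
#' @param h6 Output coupling gain; the BP output contains the term
#'   `(-h6) * x2p`.
#' @param g0,g1 Desired-BP feedforward gains into the two state equations.
#' @param g2 Desired-BP gain in the output equation.
#' @param gv Vestibular coupling gain into the second state equation.
#' @param bias Output offset (mmHg scale).
#' @param T Threshold on the first state x1 (x1 units); crossing it engages
#'   the extra feedback that triggers each systole.
#' @param S Saturation level (x1 units); must satisfy `S < T`.  Below `S` the
#'   feedback element returns 0.1, limiting the excursion and hence pulse
#'   pressure.
#' @param dt Integration step in seconds; the discrete update *is* the model.
#'   Must be positive and at most 0.005 s for stability at the default gains.
#' @param hp_fc High-pass cut-in frequency in Hz (-3 dB point) of the output
#'   chain filter.
#' @param nl_rise,nl_fall Numeric length-5 coefficient vectors (degrees 0..4)
#'   of the rising- and falling-branch quartic `f2` applied to the derivative
#'   of x2.  The constant term must be 0 on both branches.  Defaults keep the
#'   rising-branch slope above the falling-branch slope everywhere (the
#'   hysteresis of the derivative enhancement) and put the BP output on the
#'   physiological mmHg scale; see the vignette for how the cubic terms are
#'   scaled to the model's derivative amplitude `u0 = 15000`.
#'
#' @return An object of class `bp_model_params` (a validated named list).
#' @examples
#' p <- bp_model_params()
#' p$T
#' p2 <- bp_model_params(T = -100)
#' @export
bp_model_params <- function(h0 = -40.0, h1 = 19.5, h2 = -35.6, h3 = 46.15,
                            h4 = 140, h5 = -61.4, h6 = -0.05,
                            g0 = -88.05, g1 = -18.5, g2 = 0.9, gv = -88.05,
                            bias = 30, T = -40, S = -700,
                            dt = 0.001, hp_fc = 0.1,
                            nl_rise = c(0, 2.0, 0, 0.5 / 15000^2, 0),
                            nl_fall = c(0, 1.2, 0, 0.2 / 15000^2, 0)) {
  p <- list(h0 = h0, h1 = h1, h2 = h2, h3 = h3, h4 = h4, h5 = h5, h6 = h6,
            g0 = g0, g1 = g1, g2 = g2, gv = gv, bias = bias, T = T, S = S,
            dt = dt, hp_fc = hp_fc, nl_rise = nl_rise, nl_fall = nl_fall)
  class(p) <- "bp_model_params"
  validate_bp_model_params(p)
}

validate_bp_model_params <- function(p) {
  scalars <- c("h0", "h1", "h2", "h3", "h4", "h5", "h6", "g0", "g1", "g2",
               "gv", "bias", "T", "S", "dt", "hp_fc")
  for (nm in scalars) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
  }
  if (p$S >= p$T)
    stop("saturation S must lie below threshold T (S < T)", call. = FALSE)
  if (p$dt <= 0 || p$dt > 0.005)
    stop("dt must satisfy 0 < dt <= 0.005 s", call. = FALSE)
  if (p$hp_fc <= 0)
    stop("hp_fc must be positive", call. = FALSE)
  for (nm in c("nl_rise", "nl_fall")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 5L || any(!is.finite(v)))
      stop("'", nm, "' must be 5 finite polynomial coefficients (degree 0..4)",
           call. = FALSE)
    if (v[1] != 0)
      stop("'", nm, "' must have zero constant term (f2(0) = 0)",
           call. = FALSE)
  }
  p
}

#' @export
print.bp_model_params <- function(x, ...) {
  cat("Blood-pressure relaxation oscillator parameters\n")
  cat(sprintf("  core gains   h0=%g h1=%g h2=%g h3=%g h4=%g h5=%g\n",
              x$h0, x$h1, x$h2, x$h3, x$h4, x$h5))
  cat(sprintf("  drive        g0=%g g1=%g g2=%g gv=%g\n",
              x$g0, x$g1, x$g2, x$gv))
  cat(sprintf("  feedback     T=%g S=%g\n", x$T, x$S))
  cat(sprintf("  output       h6=%g bias=%g hp_fc=%g Hz\n",
              x$h6, x$bias, x$hp_fc))
  cat(sprintf("  integration  dt=%g s\n", x$dt))
  cat(sprintf("  f2 rise      (%s)\n", paste(signif(x$nl_rise, 4), collapse = ", ")))
  cat(sprintf("  f2 fall      (%s)\n", paste(signif(x$nl_fall, 4), collapse = ", ")))
  invisible(x)
}

#' Read model parameters from a config file
#'
#' Flat key-value configuration in JSON (or YAML when the `yaml` package is
#' installed; chosen by file extension).  Keys must be parameter names of
#' [bp_model_params()]; unknown keys are an error.  Values not present keep
#' their defaults.
#'
#' @param path Path to a JSON or YAML file of parameter overrides.
#' @param overrides Named list applied on top of the file (e.g. parsed from
#'   command-line flags).
#' @return A `bp_model_params` object.
#' @export
read_params_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("YAML configs require the 'yaml' package", call. = FALSE)
      yaml::read_yaml(path)
    } else {
      jsonlite::read_json(path, simplifyVector = TRUE)
    }
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(bp_model_params))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown parameter key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(bp_model_params, vals)
}
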