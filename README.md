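# relaxbp

Simulation and analysis of arterial blood pressure as a **relaxation
oscillator** under baroreflex-like feedback and vestibular (otolith) input.

Arterial pressure is a repetitive, roughly triangular waveform whose beat
frequency and amplitude are centrally regulated. `relaxbp` implements a
second-order nonlinear oscillator in which a threshold element *T* and a
saturation *S* in the feedback path (the baroreflex analogue) switch the
system between an over-damped diastolic regime and an under-damped systolic
regime, sustained by a constant *Desired BP* reference and modulated by a
vestibular input coupled into the same loop (the vestibulo-sympathetic
reflex, VSR). The package is aimed at researchers studying vaso-vagal
responses (VVR) — the simultaneous, anticompensatory fall of blood pressure
and heart rate behind vasovagal syncope — and the low-frequency (0.025–0.05
Hz) vasovagal oscillations that precede them.

The oscillator core is the discrete update

```
x1[n+1] = [1 + (-h1 - h5*f1(x1)) dt] x1[n] - h2 dt x2[n] + g1 dt BPd
x2[n+1] = (-h0 - h4*f1(x1)) dt x1[n] + [1 - h3 dt] x2[n] + g0 dt BPd + gv dt V0

f1(x1) = 0 (x1 > T), 1 (S < x1 <= T), 0.1 (x1 <= S)
```

and the pressure output is a chain applied to the derivative of `x2`: a
two-branch quartic (steeper on the rising edge — a hysteresis that sharpens
the upstroke), a 0.1 Hz first-order high-pass, an integrator `x2p`, and the
linear combination `bp = (-h6) x2p + g2 BPd + Bias` (mmHg).

Alongside the simulator the package provides stimulus generators
(Desired-BP profiles, sGVS waveforms with a strong second harmonic, tilt
trapezoids, stochastic per-beat threshold jitter), analysis operators
(systole/diastole detection, heart rate, windowed pulse pressure,
phase-plane trajectories, sequence-method baroreflex sensitivity, band
power, harmonic decomposition), a synthetic triangular-trace fixture
generator, and scenario presets (`run_scenario()`) reproducing the model's
characteristic experiments. See the vignette
(`vignettes/relaxation-oscillator-bp.Rmd`) for the model account, including
two documented calibrations (the sign of `h2` and the vestibular gain `gv`).

## Worked example

```r
library(relaxbp)

p    <- bp_model_params()                              # defaults, T = -40
stim <- stimulus_set(bpd = 50, duration = 30, dt = p$dt)
tr   <- simulate_bp(p, stim, warmup = 5)
tr
#> bp_trace: 25000 samples at dt=0.001 s (t in [5, 30] s), bp in [50.65, 91.62] mmHg

beats <- detect_beats(tr$bp, fs = 1 / p$dt, t0 = tr$t[1])
beats
#> beat_series: 163 systoles, mean RR 0.154 s (HR 6.494 Hz)

mean(pulse_pressure(beats)$per_beat$pp)
#> [1] 40.24
```

A constant Desired BP of 50 sustains a fixed 6.49 Hz oscillation (a rat
heart rate) with ~40 mmHg pulse pressure. Deepening the threshold slows the
beat but *enlarges* pulse pressure, whereas dropping Desired BP lowers
systolic level, heart rate, and pulse pressure together — the VVR pattern:

```r
m <- run_scenario(scenario_spec("threshold_step", seed = 1))$metrics
c(m$hr_pre, m$hr_post, m$pp_pre, m$pp_post)
#> [1]  6.494  5.787 40.24 62.32     # HR down, PP up: compensated slowing

m <- run_scenario(scenario_spec("vvr_bpd_step", seed = 1))$metrics
c(m$hr_pre, m$hr_post, m$pp_pre, m$pp_post)
#> [1]  5.793  5.381 62.28 54.77     # HR and PP down together: VVR
```

With per-beat Gaussian threshold jitter the model shows an emergent
positive baroreflex sensitivity (longer R-R after larger systoles), which a
low-frequency sinusoidal vestibular input inverts:

```r
sensitivity_experiment(p, v0 = "sine", v0_level = 10, seeds = 1:10)$slope_mean
#> [1] -0.155   # ms/mmHg
```

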