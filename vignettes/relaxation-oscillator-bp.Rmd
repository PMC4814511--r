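---
title: "A relaxation-oscillator model of blood pressure, heart rate, and vaso-vagal responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A relaxation-oscillator model of blood pressure, heart rate, and vaso-vagal responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relaxbp)
```

## The model

Arterial blood pressure is a repetitive, approximately triangular waveform:
a fast systolic upstroke followed by a slower relaxation to the diastolic
level.  `relaxbp` models this waveform as the output of a **relaxation
oscillator** — a second-order nonlinear system whose oscillation is sustained
not by resonance but by alternation between two regimes, switched by a
threshold element in its feedback path.  The feedback path plays the role of
the baroreflex: it carries a threshold $T$ (which gates the transition into
each systole) and a saturation $S$ (which bounds the excursion, and with it
the pulse pressure).  The oscillator is driven by a constant central
reference, *Desired BP* ($BP_d$), and by a vestibular (otolith) input $V_0$
coupled into the same feedback loop — the pathway of the
vestibulo-sympathetic reflex (VSR).

The core is the discrete-time update (the discrete system *is* the model;
no underlying continuous ODE is assumed):

$$
\begin{aligned}
x_1(n{+}1) &= \big[1 + (-h_1 - h_5 f_1(x_1))\,\Delta t\big]\,x_1(n)
  - h_2 \Delta t\, x_2(n) + g_1 \Delta t\, BP_d,\\
x_2(n{+}1) &= (-h_0 - h_4 f_1(x_1))\,\Delta t\, x_1(n)
  + (1 - h_3 \Delta t)\, x_2(n) + g_0 \Delta t\, BP_d + g_v \Delta t\, V_0,
\end{aligned}
$$

with the three-branch feedback element

$$
f_1(x_1) = \begin{cases} 0 & x_1 > T \\ 1 & S < x_1 \le T \\ 0.1 & x_1 \le S.\end{cases}
$$

Above the threshold the system has real eigenvalues (no ringing) and drives
$x_1$ downward — this is the diastolic phase.  When $x_1$ crosses $T$, the
$h_4, h_5$ feedback switches in and the system becomes under-damped
($\omega \approx 40$ rad/s at the defaults); the resulting half-swing throws
$x_1$ back above threshold and produces one systole.  The cycle repeats at
5–6.5 Hz (a rat heart rate) for a constant $BP_d$.  Deep excursions that
reach $S$ collapse the feedback gain to 0.1, clipping the swing: this is
what saturates pulse pressure at high drive.

The pressure output is shaped by a chain applied to the derivative of
$x_2$: a **two-branch quartic** $f_2$ (zero constant term, steeper on the
rising edge of the derivative than on the falling edge — a hysteresis that
sharpens the upstroke), then a **first-order high-pass filter** (cut-in
0.1 Hz, preventing integrator drift from any DC the nonlinearity
generates), then an **integrator** whose output $x_{2p}$ combines linearly
with the drive:

$$ z_2(n) = (-h_6)\, x_{2p}(n) + g_2\, BP_d + \mathrm{Bias}. $$

$z_2$ is the BP reference signal (mmHg scale); there is no hemodynamic
plant downstream — the reference *is* the model output.

## Parameter defaults and two documented calibrations

`bp_model_params()` carries the published gain set
($h_0=-40$, $h_1=19.5$, $h_3=46.15$, $h_4=140$, $h_5=-61.4$, $h_6=-0.05$,
$g_0=-88.05$, $g_1=-18.5$, $g_2=0.9$, Bias $=30$, $T=-40$, $S=-700$,
high-pass cut-in 0.1 Hz) with $\Delta t = 1$ ms, matching the 1 kHz
acquisition rate of the recordings the model describes.  Two entries are
package calibrations rather than quoted values, and both are load-bearing:

**The sign of $h_2$.**  With $h_2 = +35.6$, the above-threshold subsystem
has a stable focus at $x_1 \approx +49$ for $BP_d = 50$: from the resting
initial state the trajectory settles there, never reaches $T = -40$, and no
oscillation ever starts; trajectories forced below threshold fall into a
fast chatter cycle pinned at $S$ that is insensitive to $T$.  Neither
behaviour is the documented mechanism (non-oscillatory above-threshold
dynamics driving $x_1$ to negative levels; under-damped dynamics below
threshold; frequency and amplitude strongly modulated by $T$).  An
exhaustive scan of all $2^7$ sign assignments of
$\{h_0,h_2,h_3,h_4,h_5,g_0,g_1\}$ finds exactly one dynamical system (up to
a state reflection) with those properties, reached by flipping only $h_2$.
With $h_2 = -35.6$ the model self-starts from the zero state, oscillates at
6.49 Hz at the defaults, at 5.79 Hz for $T=-100, BP_d=50$ and 5.38 Hz for
$T=-100, BP_d=40$, and slows while growing in amplitude as $T$ deepens.
The package therefore defaults to $h_2 = -35.6$ and treats the positive
value as a sign typo.

**The vestibular gain $g_v$.**  No value for $g_v$ is available (a printed
$g_3 = 0.1$ appears in no equation; coupling $V_0$ through 0.1 against
$g_0 BP_d \approx -4400$ would make a $V_0$ of 10 a 0.02% perturbation with
no observable effect).  The model's own description — vestibular input
"has a similar effect as modulating Desired BP" — pins the natural scale:
the package sets $g_v = g_0$, making one unit of $V_0$ equipotent with one
mmHg of $BP_d$.

**$f_2$ coefficients.**  The quartic's coefficients were never published.
The defaults use linear terms 2.0 (rising) and 1.2 (falling), which place
the output in the physiological range (pulse pressure $\approx 40$ mmHg at
$BP_d = 50$), plus cubic enhancements $0.5/u_0^2$ and $0.2/u_0^2$ with
$u_0 = 15000$, the typical peak $|\dot x_2|$ at baseline — i.e. a
$\sim 25\%$ extra sharpening at full derivative swing, more on the rising
branch.  `fit_f2()` re-estimates both branches from paired
derivative data by least squares when users have recordings to fit.

## Stimuli

* `make_bpd_profile()` — piecewise-constant Desired-BP with linear ramps;
  a transient drop (e.g. 50 to 40 mmHg) reproduces the vaso-vagal response
  (VVR): systolic level, heart rate, and pulse pressure fall *together*,
  the anticompensatory signature.
* `make_sgvs_input()` — sinusoidal galvanic vestibular stimulation as a
  central otolith signal: fundamental (default 0.025 Hz) plus a strong
  second harmonic (default ratio 1.5).  The default fundamental amplitude
  3 sits at the middle of the linear range of the measured
  modulation-vs-amplitude curve (`vsr_curve()`), which is linear up to
  amplitude $\approx 6$ and saturates beyond.
* `make_tilt_input()` — a trapezoid for sustained head-up tilt.
* `make_threshold_process()` — constant, stepped, or stochastic threshold.
  The stochastic mode redraws a zero-mean Gaussian perturbation
  (default sd 5 $x_1$-units) once per beat, at the upward threshold
  recrossing that ends the beat's triggered phase, and holds it until the
  next beat.  This per-beat jitter produces slow variability of systolic
  level (Mayer-wave-like) and is the substrate of the sensitivity analysis
  below.

## Baroreflex sensitivity and the vestibular conditions

`baroreflex_sensitivity()` implements the sequence method: each R-R
interval is regressed on the systolic pressure of the beat that opens it
(lag 0).  Slopes are quoted in ms/mmHg; with R-R in seconds the same slope
is 1000 times smaller.  Under per-beat threshold jitter a deeper-than-usual
threshold makes both the current systole larger and the following interval
longer, so the model exhibits a positive, compensatory slope without any
explicit baroreflex-gain element — an emergent property.

`sensitivity_experiment()` averages the slope over seeds (single
realizations are noisy).  The three standard conditions are $V_0 = 0$,
constant $V_0 = 10$, and a pure 0.025 Hz sinusoid of amplitude 10 — the
sinusoid uses the same level as the printed constant input, since its own
amplitude was never published and the sGVS amplitude 3 is too weak for the
modulation to dominate the jitter.  In this realization the sinusoidal
input robustly *inverts* the slope (negative in every seed), while a
constant input leaves it positive but slightly below the no-input value;
the slope-vs-drive relation peaks near $BP_d = 50$, so both signs of an
equipotent constant input lower it.  A reported near-doubling under
constant input is not reproduced by this realization — see Limitations.

## What the synthetic fixture generator does and does not emulate

`synth_triangular_bp()` emits idealized triangular beats with exactly known
systole/diastole times, optional per-beat interval and level modulation,
and optional Gaussian measurement noise.  It validates the analysis stack
(detection, HR, pulse pressure) against ground truth.  It does *not*
emulate dicrotic notches, respiratory modulation, baseline wander, or
movement artefacts of real pressure recordings; passing these tests shows
the operators are correct on clean morphology, not that detection
parameters are optimal for any particular recording system.

## Numerical choices

* $\Delta t = 1$ ms; the explicit update is the model, so `dt` is a model
  parameter, capped at 5 ms where the default gains remain stable.
* Initial state: all states zero, falling branch; the first 5 s (warmup)
  are discarded before analysis.
* High-pass: bilinear transform with the cut-in as the $-3$ dB point
  (gain $1/\sqrt2$ at 0.1 Hz, DC gain 0); warping is negligible at
  0.1 Hz / 1 kHz.
* Hysteresis branch rule: rising while the derivative of $x_2$ increased
  since the previous step, falling otherwise (ties fall).
* Beat detection: local maxima with topographic prominence $\ge 2$ mmHg and
  separation $\ge$ 0.08 s (rat heart rates are 3–6 Hz); when two candidates
  collide the higher wins.  Diastole is the minimum between consecutive
  systoles.
* Pulse-pressure windows (default 25 s) are non-overlapping.
* Spectral estimates are plain periodograms after mean removal, no taper:
  records are long and the tones of interest sit far from band edges.
* Degenerate inputs: constant/empty traces yield empty beat series (not
  errors); a state excursion beyond $10^{12}$ or any non-finite state
  aborts the run with the step index.

## Scenario presets and problem sizes

`run_scenario()` composes stimuli, simulation, and analysis.  Durations
are chosen for stable beat statistics at desk scale: baseline 30 s; step
scenarios 100 s on each side of the transition; sGVS and VSR-sweep runs
200 s (5 stimulus periods at 0.025 Hz, first period discarded); the
pulse-pressure sweep covers $BP_d = 20..150$ at $T = -100$, 40 s per level
(at the default $T = -40$ the oscillation dies near $BP_d \approx 90$
before the saturation branch ever engages, so no saturation regime exists
there; at $T = -100$ excursions reach $S$ at $BP_d \gtrsim 130$ and pulse
pressure flattens).  Sensitivity presets run 10 seeds of 60 s each; the
acceptance script uses 20 seeds of 120 s for a tighter estimator.

## Limitations

* The model emits a BP *reference* signal; there is no heart/vessel plant,
  no Desired-HR pathway, and no mechanism converting sustained vestibular
  input into a drop in Desired BP (a VVR is elicited by prescribing the
  $BP_d$ drop).
* $T$ is an externally supplied process; a functional dependence of the
  threshold on desired heart rate and state is not modelled (no functional
  form is available).
* The quartic $f_2$ coefficients and $g_v$ are calibrations (above), so
  absolute output scales (pulse pressure in mmHg, slopes in ms/mmHg) carry
  that calibration.
* Under constant vestibular input this realization does not reproduce an
  *increase* of the sequence-method slope; the sign pattern across the
  three vestibular conditions (positive, positive, negative) is robust,
  the magnitude under non-zero vestibular input is not.
* Pulse pressure saturates only where the drive is deep enough for
  excursions to reach $S$; the default-threshold regime instead loses the
  oscillation at high drive (a reset, not a clip).

## A minimal session

```{r example, eval = FALSE}
p <- bp_model_params()                        # defaults, T = -40
stim <- stimulus_set(bpd = 50, duration = 30, dt = p$dt)
tr <- simulate_bp(p, stim, warmup = 5)
beats <- detect_beats(tr$bp, fs = 1 / p$dt, t0 = tr$t[1])
1 / mean(beats$rr)                            # ~6.49 Hz
mean(pulse_pressure(beats)$per_beat$pp)       # ~40 mmHg
baroreflex_sensitivity(beats)                 # needs jitter for variance
```
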