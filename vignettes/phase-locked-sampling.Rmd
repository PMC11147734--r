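---
title: "Simulating and measuring resonant-scanner jitter under phase-locked sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and measuring resonant-scanner jitter under phase-locked sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scanlock)
```

## The problem

A resonant scanner oscillates sinusoidally at a fixed mechanical resonance
(8 or 12 kHz in the systems this package emulates) and provides the fast
axis of a laser-scanning microscope. Because the scanner is free-running,
the microscope cannot place pixels by commanding the mirror; it must infer
the mirror position from a once-per-cycle TTL position-feedback edge and
from the sample clock. Three distinct error sources corrupt that inference:

* **mirror jitter** — the mirror's own turnaround time fluctuates cycle to
  cycle (vibration, inertia, thermal effects);
* **feedback jitter** — broadband electrical noise on the feedback edge
  relative to the true turnaround;
* **synchronization jitter** — when the pixel sampling clock free-runs
  relative to the line trigger, the first sample of each line lands a
  random fraction of a sample period after the trigger, a bounded error
  uniform on one sample period (±0.5 samples about its mean).

A zero-delay phase-locked loop (PLL) fed by the position feedback removes
the latter two: it low-passes the edge timing (denoising the feedback) and
synthesizes an integer multiple N of the line rate as the sampling clock,
so the sampling grid breathes with the scanner and the trigger-to-sample
phase is constant. scanlock simulates this entire chain and implements the
metrology used to quantify it, so the suppression mechanism and the
measurement procedures can be exercised and validated without hardware.

## The model

**Scanner kinematics.** The fast angle is $\theta(t) = \Theta
\sin(2\pi\varphi(t))$ with optical half-angle $\Theta$ (10° for the 8 kHz
scanner at full range, 5° for the 12 kHz one). The phase $\varphi$
accumulates through per-cycle turnaround times that carry frequency drift
(a fractional-frequency random walk by default, with a 2e-9 per-cycle step
so drift stays below about a ppm per second — scanner frequency changes
only very gradually) and white per-cycle turnaround timing noise (mirror
jitter). Between turnarounds the phase is interpolated linearly; this is
the simplest model consistent with "the turnaround time is the observable"
and makes the feedback-edge oracle exact.

**Cycle origin.** One constant (`TURNAROUND_PHASE = 0.75`) fixes the
convention everywhere: the feedback edge fires at the $-\Theta$ turnaround
and the forward sweep is the following half cycle, running $-\Theta \to
+\Theta$. Which turnaround carries the edge is not observable from any of
the statistics this package computes; the choice is isolated so it can be
flipped in one place.

**Slow axis.** Deterministic wobble is locked to fast-axis phase: an
elliptical path (drive-signal crosstalk; semi-minor axis ~400 µrad in the
worst cabling configuration) plus a high-frequency transverse oscillation
(~924 kHz, ~5 µrad, realized as the nearest integer number of oscillations
per cycle — 77 at 12 kHz — so that equal phase implies equal wobble).
Stochastic slow-axis jitter is a per-cycle offset, white across cycles.

**Feedback electronics.** White per-edge timing noise (3.38 ns RMS
reproduces the measured feedback-versus-optical jitter of an 8 kHz
scanner) plus optional narrowband sinusoidal components with seeded random
phase, emulating the 20–200 Hz band structure of driver-electronics noise.

**The PLL.** A discrete type-II (proportional–integral) loop updated once
per reference edge — the natural model for a phase detector that sees a
kHz edge stream. With phase predictor $p$, period integrator $\tau$ and
error $e_n = r_n - p_n$:
$\tau_{n+1} = \tau_n + k_i e_n$, $p_{n+1} = p_n + \tau_{n+1} + k_p e_n$.
The reference-to-output transfer is, exactly,
$$H(z) = \frac{(k_p + k_i)(z-1) + k_i}{(z-1)^2 + (k_p+k_i)(z-1) + k_i},$$
which `jitter_transfer()` evaluates on the unit circle; `pll_lock()` is the
time-domain realization and the two are tested against each other (a
sinusoidal probe agrees within 1%). Gains map from `(loop_bandwidth,
damping)` by setting the natural frequency so the closed-loop −3 dB point
equals the loop bandwidth: $\omega_n = 2\pi B / g(\zeta)$ with
$g(\zeta)=\sqrt{1+2\zeta^2+\sqrt{(1+2\zeta^2)^2+1}}$, then
$k_i=(\omega_n T)^2$, $k_p = 2\zeta\omega_n T - k_i$. DC gain is exactly 1
(drift is tracked), and jitter above the bandwidth is strongly attenuated
(≥ 20 dB at 10× bandwidth at damping 0.7). `effective_averaging_periods()`
converts the transfer's equivalent-noise bandwidth into the length of the
rectangular averager with the same white-jitter variance reduction; a
100 Hz loop on a 12 kHz reference at damping 0.7 averages ≈ 36 periods,
consistent with the "a few tens of periods" regime the hardware loop
operates in. The loop order and damping of the hardware part are not
public, so damping is an explicit knob, defaulting to 0.7.

Output clocks subdivide each *predicted* x1 period into N uniform
intervals, so a change in scanner period is cancelled by a matching change
in sampling period — the heart of the suppression mechanism. The first
`max(1000 edges, 20/bandwidth seconds)` are discarded as acquisition
transient; the hardware behavior during lock acquisition is not modeled.

**Acquisition.** `acquire_line_scan()` triggers each line on either the
raw feedback edge or the PLL x1 edge, starts sampling at the first clock
edge at or after the trigger (ties go to the current edge), and fills a
fixed count S of samples per cycle — S/2 forward, S/2 backward — with the
phantom intensity at the true mirror angle, plus Poisson photon noise.
Sampling is instantaneous point sampling: real detectors integrate, but
all the jitter metrology depends only on sample timing, and point sampling
keeps every oracle exact. The off-by-one trigger effect and the beat
between an unsynchronized clock and the line rate emerge from this
mechanism rather than being injected.

Two controlled injection hooks exist for metrology validation:
`injected_shift_samples` delays the mirror trajectory of individual cycles
(producing exact fractional image shifts — the forward image moves $+dx$,
the backward image $-dx$), and `injected_trigger_jitter_samples` moves the
trigger edges themselves (exercising quantization). They are distinct
because the two physical mechanisms really are distinct.

**Dewarping.** Forward sample $s \in [0, S/2)$ sits at angle
$-\Theta\cos(2\pi s/S)$ and maps to pixel $p = n_{px}(\theta+\Theta)/(2\Theta)$;
the backward map is the mirror image. `dewarp_line()` resamples by
interval-averaged (mean-preserving) rebinning: flat fields stay flat,
total intensity (value × dwell) is conserved, and a slit at scan center
widens by the local map derivative $\pi n_{px}/S$.

## The metrology

* `locate_edge_subsample()` — Fourier zero-pad upsampling (default ×16, a
  documented convention; the choice of kernel matters little above ×8)
  then linear interpolation of the half-amplitude crossing. The linear
  trend joining the record's endpoints is removed before the FFT and
  restored after, because an edge waveform is not periodic and the wrap
  discontinuity would otherwise ring into the transition.
* `locate_peak_subsample()` — upsampling, then matched-filter smoothing
  (a Gaussian kernel matched to the peak's own measured FWHM) and a
  least-squares parabolic vertex over the smoothed top. The plain
  three-point parabola is noise-limited well above the photon limit; the
  matched-filter variant operates near the Cramér–Rao bound (RMS < 0.1
  samples at peak SNR 10) while remaining exact for symmetric noiseless
  peaks.
* `bidirectional_misalignment()` — per cycle, the backward half-line is
  reversed, both halves upsampled and mean-subtracted, and the
  cross-correlation peak refined by a three-point parabola. With a fixed
  number of samples per sweep, a line shift of $dx$ moves the forward and
  reversed-backward images in opposite directions, so the misalignment
  changes by $2\,dx$ — the "twice relation". The reported per-cycle value
  is raw and includes the record's constant alignment offset (+1 sample
  for a slit at scan center on an even-S lattice, because forward sample
  $s$ mirrors onto backward sample $S-1-s$, whose angle equals that of
  forward sample $s+1$); jitter statistics use the mean-removed series.
* `jitter_psd()` — Welch averaged periodogram, Hann window, 50% overlap,
  one-sided, normalized so integrated power equals series variance.
* `track_2d_pulses()` / `fit_wobble_ellipse()` — camera-frame pulse
  tracking (smoothed candidate detection, cluster suppression, separable
  2D subsample localization of the pulse nearest scan center) and a
  numerically stabilized direct least-squares conic fit (Halir–Flusser)
  with per-axis pre-scaling, which keeps the extreme wobble aspect ratios
  (semi-major ~0.17 rad against semi-minor ~4e-4 rad) well conditioned.
* `fwhm()` / `averaging_broadening_curve()` — linear-interpolated
  half-maximum widths (background from the outer 10% of the window) and
  the broadening of block-averaged lines. For Gaussian line jitter
  $\sigma_j$ the asymptotic width is $\sqrt{w_0^2 + 8\ln 2\,\sigma_j^2}$;
  finite averaging depths sit strictly between the single-frame width and
  that asymptote.
* Mean removal — not detrending — defines jitter throughout; slow drift
  is analyzed in the PSD domain instead.

Jitter figures convert between samples, seconds and radians through the
scan-center slope $t = \theta/(\Theta\,2\pi f)$ (`convert_units()`); e.g.
0.046 samples at 80.4 MHz is 0.57 ns, and 5.143 µrad at 12 kHz with
$\Theta = 5°$ is 0.78 ns. Pixel-equivalent reporting is provided only
through the dewarp-map derivative: the published pixel columns for these
scanners imply optical scale factors that are not stated and are not
internally consistent between scanner models, so they are not used for
validation.

## What the synthetic world does and does not establish

The generator's defaults are the stated conditions of the hardware it
emulates: 8 kHz/±10° and 12 kHz/±5° scanners, 3.38 ns feedback edge noise,
400 µrad elliptical wobble, ~924 kHz/5 µrad transverse oscillation,
13.49 µrad slow-axis jitter, 100–200 Hz loop bandwidths, ×1250 and ×6700
clock multiplication. The 12 kHz amplitude of ±5° is *inferred* from the
published angle↔time ratios, not stated in any text, and is documented as
a default rather than a fact. Line-scan experiments run at a scaled-down
200 samples per cycle (2.4 MHz instead of 80.4 MHz): every mechanism under
test — quantization, off-by-one, beat, the twice relation, broadening —
lives in sample units and is unaffected by the scale-down; only
sample-to-nanosecond conversions change, and those are exercised at the
real 80.4 MHz rate in the unit conversions.

A green suite establishes that the *mechanisms* behave as derived —
bounded uniform synchronization error, its elimination under full phase
locking, the loop transfer, parameter recovery by the estimators — not
that any particular piece of hardware meets a number. Absolute hardware
jitter values enter only as injected truths with recovery tolerances.
Camera frames render the forward and backward sweeps into separate images
(as if pulse-gated); a physical camera integrates both into one frame and
resolves them only where wobble separates the paths. Detector impulse
response, analog filtering and digitizer quantization beyond photon noise
are out of scope.

## Numerical choices and degenerate inputs

* All randomness flows from one run seed through named substreams
  (`substream_seed()`), so disabling one noise source never perturbs the
  draws of another, and identical configs and seeds give byte-identical
  outputs.
* Edge series reject non-monotone timestamps or spacings more than 20%
  from nominal; the PLL additionally rejects gaps over 1.5 periods with
  the offending cycle index. Failed per-line fits are excluded and
  counted, never fatal.
* The trigger-to-sample rule is "first clock edge at or after the
  trigger", with a 1e-9-sample tolerance so exact ties go to the current
  edge.
* Collinear input to the ellipse fit returns a flagged degenerate fit with
  zero semi-minor axis; plateaued waveforms (more than 10% of the window
  within 0.1% of the maximum) are rejected by the peak localizer, while a
  two-sample tie — a symmetric vertex between samples — is accepted.
* The equivalent-noise bandwidth is integrated numerically from the exact
  discrete transfer; the "doubling the bandwidth halves the averaging"
  law holds in the bandwidth ≪ edge-rate regime and bends by a few percent
  once the loop bandwidth reaches a few percent of the edge rate.

## Known limitations

* The phase model is piecewise-linear between turnarounds; intra-cycle
  phase noise finer than once-per-cycle is not modeled.
* Mirror jitter is timing-only; amplitude jitter is not modeled (only
  timing/angle jitter is quantified by the metrology this package
  implements).
* The PLL has no oscillator phase-noise floor, spurs, or fractional-N
  behavior; zero-delay is modeled as exact.
* The powder phantom is a random Gaussian-emitter field, static across
  cycles; real fluorescent powder bleaches and has structured granularity.
* TIFF support is deliberately the minimal baseline subset this package
  writes (16-bit grayscale, uncompressed, one strip per page).
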