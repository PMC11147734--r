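# scanlock

Resonant-scanner jitter simulation and phase-locked-sampling metrology for
laser-scanning microscopy.

Resonant scanners (8–12 kHz sinusoidal mirrors) give laser-scanning
microscopes their speed, but they are free-running: pixel placement must be
inferred from a once-per-cycle TTL position-feedback edge and the sampling
clock. Three error sources corrupt that inference — **mirror jitter**
(turnaround timing noise of the mirror itself), **feedback jitter**
(electrical noise on the feedback edge) and **synchronization jitter** (the
bounded ±0.5-sample error when the sampling clock free-runs relative to the
line trigger). A zero-delay phase-locked loop (PLL) fed by the feedback
signal denoises the line clock and synthesizes an integer-multiple sampling
clock, holding the trigger-to-sample phase constant and suppressing the
dominant jitter terms entirely in hardware.

scanlock lets you exercise that whole story without a microscope. It is two
packages in one:

* a **simulator** — scanner kinematics with drift, mirror jitter, slow-axis
  wobble/crosstalk and feedback noise ([`scanner_spec()`],
  [`simulate_trajectory()`], [`generate_feedback_edges()`]); a discrete
  type-II zero-delay PLL with exact closed-form jitter transfer
  ([`pll_config()`], [`pll_lock()`], [`jitter_transfer()`]); and phantom
  acquisition (fixed slit, fluorescent powder, pulsed-laser camera frames)
  under the four line-trigger × sampling-clock configurations
  ([`acquire_line_scan()`], [`acquire_camera_frames()`],
  [`build_dewarp_map()`]);
* a **metrology suite** — subsample edge/peak localization, per-line slit
  tracking, bidirectional (forward/backward) misalignment via
  cross-correlation, Welch jitter spectra, wobble ellipse fitting,
  intra-cycle jitter and FWHM broadening under frame averaging
  ([`locate_peak_subsample()`], [`slit_center_series()`],
  [`bidirectional_misalignment()`], [`jitter_psd()`],
  [`fit_wobble_ellipse()`], [`averaging_broadening_curve()`]).

The metrology half also reads externally produced data in the documented
layouts (edge-series CSV, 16-bit grayscale TIFF line-scan stacks).

## Worked example

Simulate a 12 kHz scanner whose sampling clock either free-runs or is
phase-locked, and measure the synchronization jitter both ways:

```r
library(scanlock)

spec <- scanner_spec(nominal_frequency = 12000, amplitude = 5 * pi / 180,
                     drift = drift_model("random_walk"))
S    <- 200L                       # samples per cycle (scaled-down geometry)
slit <- phantom_slit(center = 0, width = 0.5 * spec$amplitude * 2 * pi / S,
                     psf_sigma = 2.5 * spec$amplitude * 2 * pi / S,
                     photon_scale = 8000)

free <- acquire_line_scan(spec, trigger_config("pll_x1", S),
                          clock_spec("free_running", S * 12000),
                          slit, n_cycles = 10000, seed = 1)
lock <- acquire_line_scan(spec, trigger_config("pll_x1", S),
                          clock_spec("pll_locked", S * 12000),
                          slit, n_cycles = 10000, seed = 1)

e <- free$quant_error_samples
sqrt(mean((e - mean(e))^2))            # 0.2887531  (uniform: 1/sqrt(12) = 0.2887)
max(abs(e - mean(e)))                  # 0.5035625  (bounded +/- 0.5 sample)
sqrt(mean(lock$quant_error_samples^2)) # 0          (phase-locked: no sync jitter)

percent_reduction_label(0.324, 0.046)  # "86%" -- feedback-triggered asynchronous
                                       # vs fully phase-locked, in samples RMS
```

The first three numbers are the synchronization-jitter story in miniature:
an unsynchronized clock gives a uniform, bounded ±0.5-sample trigger
quantization error (RMS 1/√12 ≈ 0.289 samples); phase-locking both trigger
and clock removes it to machine precision. The last line is the headline
arithmetic comparing the unsuppressed and fully suppressed imaging
configurations (0.324 → 0.046 samples RMS).

Canned end-to-end experiment drivers reproduce the characteristic result
tables and write CSV/JSON/TIFF bundles:

```r
res <- run_experiment(experiment_config("fig6", seed = 1), "out/fig6")
res$summary
#    line_trigger sampling_clock samples_rms   time_ns ...
#  1 Pos. feedback  Asynchronous  0.454      189.3
#  2 Pos. feedback           PLL  0.486      202.7
#  3           PLL  Asynchronous  0.076       31.8
#  4           PLL           PLL  0.049       20.3
```

A thin CLI wraps the same drivers:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","scanlock.R",package="scanlock"))')" \
    experiment fig6 --seed 1 --out out/fig6
```

## Documentation

The methods vignette (`vignettes/phase-locked-sampling.Rmd`) describes the
scanner and PLL models and their assumptions, the estimator designs and
numerical choices, what the synthetic world does and does not establish,
and known limitations.
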