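#' Resonant scanner specification
#'
#' Describes a resonant scanner's kinematics and noise: the fast axis is a
#' sinusoid at `nominal_frequency` with optical half-angle `amplitude`;
#' per-cycle turnaround timing noise (`mirror_jitter_rms`), slow frequency
#' drift, slow-axis wobble/crosstalk, and electronic feedback noise are all
#' independently controllable.  Defaults describe an 8 kHz scanner driven at
#' its maximum +/-10 degree optical scan range; a 12 kHz scanner is
#' conventionally run at +/-5 degrees (see [scanner_12k()]).
#'
#' @param nominal_frequency scan frequency in Hz.
#' @param amplitude optical half-angle Theta in radians.
#' @param mirror_jitter_rms RMS of the per-cycle turnaround timing jitter in
#'   seconds (white in cycle index).
#' @param drift a [drift_model()].
#' @param wobble a [wobble_spec()].
#' @param feedback_noise a [feedback_noise_spec()].
#' @return object of class `scanner_spec`.
#' @export
scanner_spec <- function(nominal_frequency = 8000,
                         amplitude = 10 * pi / 180,
                         mirror_jitter_rms = 0,
                         drift = drift_model("none"),
                         wobble = wobble_spec(),
                         feedback_noise = feedback_noise_spec()) {
  stopifnot(nominal_frequency > 0, amplitude > 0, mirror_jitter_rms >= 0)
  structure(list(nominal_frequency = nominal_frequency,
                 amplitude = amplitude,
                 mirror_jitter_rms = mirror_jitter_rms,
                 drift = drift, wobble = wobble,
                 feedback_noise = feedback_noise),
            class = "scanner_spec")
}

#' @rdname scanner_spec
#' @param ... overrides passed to [scanner_spec()].
#' @export
scanner_12k <- function(...) {
  args <- utils::modifyList(
    list(nominal_frequency = 12000, amplitude = 5 * pi / 180), list(...))
  do.call(scanner_spec, args)
}

#' Frequency drift model
#'
#' Resonant scanners are free-running and drift slowly in frequency.  The
#' per-cycle fractional frequency deviation is either zero (`none`), a
#' driftless random walk (`random_walk`, per-cycle step RMS
#' `random_walk_step_rms`; the default step of 2e-9 per cycle keeps drift
#' below about a ppm per second at kHz line rates), or a deterministic
#' sinusoid (`sinusoidal`).
#'
#' @param kind one of `"none"`, `"random_walk"`, `"sinusoidal"`.
#' @param random_walk_step_rms dimensionless per-cycle fractional step.
#' @param sinusoidal_amplitude dimensionless fractional frequency deviation.
#' @param sinusoidal_frequency Hz.
#' @export
drift_model <- function(kind = c("none", "random_walk", "sinusoidal"),
                        random_walk_step_rms = 2e-9,
                        sinusoidal_amplitude = 0,
                        sinusoidal_frequency = 1) {
  kind <- match.arg(kind)
  stopifnot(random_walk_step_rms >= 0, sinusoidal_amplitude >= 0,
            sinusoidal_frequency > 0)
  structure(list(kind = kind,
                 random_walk_step_rms = random_walk_step_rms,
                 sinusoidal_amplitude = sinusoidal_amplitude,
                 sinusoidal_frequency = sinusoidal_frequency),
            class = "drift_model")
}

#' Slow-axis wobble specification
#'
#' Deterministic wobble is locked to the fast-axis phase: an elliptical path
#' (90-degree-shifted sinusoid at the scan frequency, semi-minor axis
#' `ellipse_semi_minor`, caused by galvo/resonant drive-signal crosstalk)
#' plus a high-frequency transverse oscillation (e.g. ~924 kHz, ~5 urad on a
#' 12 kHz scanner).  The HF oscillation is realized as the nearest integer
#' lock `round(hf_frequency / scan_frequency)` oscillations per scan cycle,
#' so identical fast-axis phase always reproduces the identical
#' deterministic slow angle.  `slow_axis_jitter_rms` adds a stochastic
#' per-cycle offset.
#'
#' @param ellipse_semi_minor radians.
#' @param hf_oscillation_frequency Hz.
#' @param hf_oscillation_amplitude radians.
#' @param slow_axis_jitter_rms radians (per-cycle, white).
#' @export
wobble_spec <- function(ellipse_semi_minor = 0,
                        hf_oscillation_frequency = 924e3,
                        hf_oscillation_amplitude = 0,
                        slow_axis_jitter_rms = 0) {
  stopifnot(ellipse_semi_minor >= 0, hf_oscillation_frequency > 0,
            hf_oscillation_amplitude >= 0, slow_axis_jitter_rms >= 0)
  structure(list(ellipse_semi_minor = ellipse_semi_minor,
                 hf_oscillation_frequency = hf_oscillation_frequency,
                 hf_oscillation_amplitude = hf_oscillation_amplitude,
                 slow_axis_jitter_rms = slow_axis_jitter_rms),
            class = "wobble_spec")
}

#' Electronic feedback-noise specification
#'
#' The position-feedback TTL edges carry broadband electrical noise on top of
#' the true mirror turnaround times: an additive white component
#' (`white_rms`, independent per edge) plus optional narrowband components
#' given as a list of `c(center_hz, rms_s)` pairs, realized as sinusoids in
#' edge time with random phase per run.
#'
#' @param white_rms seconds.
#' @param band_components list of numeric pairs `c(center_hz, rms_s)`.
#' @export
feedback_noise_spec <- function(white_rms = 0, band_components = list()) {
  stopifnot(white_rms >= 0)
  for (bc in band_components) {
    stopifnot(length(bc) == 2L, bc[1] > 0, bc[2] >= 0)
  }
  structure(list(white_rms = white_rms, band_components = band_components),
            class = "feedback_noise_spec")
}

## Per-cycle fractional frequency deviation d_k, k = 1..n (substreamed).
drift_deviation <- function(drift, n, T0, seed) {
  switch(drift$kind,
         none = numeric(n),
         random_walk = {
           if (drift$random_walk_step_rms == 0) numeric(n) else
             with_substream(seed, "drift",
                            cumsum(stats::rnorm(n, 0, drift$random_walk_step_rms)))
         },
         sinusoidal = drift$sinusoidal_amplitude *
           sin(2 * pi * drift$sinusoidal_frequency * (seq_len(n) - 1) * T0))
}

## The cycle skeleton shared by trajectory, edge and acquisition simulation:
## the true -Theta turnaround times (drift + mirror jitter) for cycles
## 0..n-1; turnaround k sits at fast-axis phase k + TURNAROUND_PHASE.
cycle_skeleton <- function(spec, n_cycles, seed) {
  T0 <- 1 / spec$nominal_frequency
  d <- drift_deviation(spec$drift, n_cycles, T0, seed)
  periods <- T0 / (1 + d)
  base <- TURNAROUND_PHASE * periods[1L] + c(0, cumsum(periods[-n_cycles]))
  eta <- if (spec$mirror_jitter_rms > 0) {
    with_substream(seed, "mirror", stats::rnorm(n_cycles, 0, spec$mirror_jitter_rms))
  } else numeric(n_cycles)
  ## turnaround_base: drift only -- the smooth timeline a PLL averaging many
  ## cycles effectively follows; turnaround_true adds per-cycle mirror jitter
  list(T0 = T0, periods = periods, turnaround_base = base,
       turnaround_true = base + eta, frac_dev = d, n_cycles = n_cycles)
}

## Noisy feedback edge times from a skeleton (electronic noise substreams).
feedback_times_from_skeleton <- function(spec, skel, seed) {
  fb <- skel$turnaround_true
  fn <- spec$feedback_noise
  n <- length(fb)
  if (fn$white_rms > 0) {
    fb <- fb + with_substream(seed, "feedback_white",
                              stats::rnorm(n, 0, fn$white_rms))
  }
  if (length(fn$band_components)) {
    phases <- with_substream(seed, "feedback_band",
                             stats::runif(length(fn$band_components), 0, 2 * pi))
    for (i in seq_along(fn$band_components)) {
      bc <- fn$band_components[[i]]
      fb <- fb + bc[2] * sqrt(2) * sin(2 * pi * bc[1] * skel$turnaround_true + phases[i])
    }
  }
  fb
}

## Fast-axis phase (cycle units) at arbitrary times, by piecewise-linear
## interpolation through the true turnarounds (phase k + TURNAROUND_PHASE),
## linearly extrapolated by one period at both ends.
phase_at <- function(skel, times) {
  n <- length(skel$turnaround_true)
  u <- c(skel$turnaround_true[1L] - skel$periods[1L],
         skel$turnaround_true,
         skel$turnaround_true[n] + skel$periods[n])
  p <- TURNAROUND_PHASE + c(-1, seq_len(n) - 1, n)
  if (min(times) < u[1L] - skel$T0 || max(times) > u[n + 2L] + skel$T0) {
    stop("phase_at: requested times extend beyond the simulated cycle skeleton")
  }
  stats::approx(u, p, xout = times, rule = 2)$y
}

## Slow-axis angle at given fast-axis phases: deterministic phase-locked
## wobble plus stochastic per-cycle offsets.
slow_angle_at <- function(spec, phi, n_cycles, seed) {
  w <- spec$wobble
  slow <- w$ellipse_semi_minor * cos(2 * pi * phi)
  if (w$hf_oscillation_amplitude > 0) {
    k_hf <- max(1, round(w$hf_oscillation_frequency / spec$nominal_frequency))
    slow <- slow + w$hf_oscillation_amplitude * sin(2 * pi * k_hf * phi)
  }
  if (w$slow_axis_jitter_rms > 0) {
    idx <- floor(phi + 1 - TURNAROUND_PHASE)  # cycle membership
    offs <- with_substream(seed, "slow_axis",
                           stats::rnorm(n_cycles + 2L, 0, w$slow_axis_jitter_rms))
    slow <- slow + offs[pmax(1L, pmin(n_cycles + 2L, idx + 2L))]
  }
  slow
}

#' Simulate the mirror trajectory
#'
#' Evaluates the fast- and slow-axis mirror angles at the requested times.
#' The fast angle is `Theta * sin(2*pi*phi(t))` where the accumulated phase
#' `phi` passes through the jittered, drifting turnaround times; the slow
#' angle is the phase-locked elliptical crosstalk component (90 degrees
#' shifted from the fast axis) plus the high-frequency transverse
#' oscillation plus a stochastic per-cycle slow-axis offset.  Given the same
#' seed, the trajectory is the one whose turnarounds
#' [generate_feedback_edges()] reports.
#'
#' @param spec a [scanner_spec()].
#' @param times strictly increasing numeric vector of times in seconds.
#' @param seed integer run seed.
#' @return object of class `trajectory`: a data frame with columns `time_s`,
#'   `fast_angle_rad`, `slow_angle_rad`.
#' @export
simulate_trajectory <- function(spec, times, seed = 1L) {
  times <- as.numeric(times)
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("simulate_trajectory: times must be strictly increasing (first violation at index ",
         which(diff(times) <= 0)[1L] + 1L, ")")
  }
  n_cycles <- max(2L, ceiling(max(times) * spec$nominal_frequency) + 2L)
  skel <- cycle_skeleton(spec, n_cycles, seed)
  phi <- phase_at(skel, times)
  structure(data.frame(time_s = times,
                       fast_angle_rad = spec$amplitude * sin(2 * pi * phi),
                       slow_angle_rad = slow_angle_at(spec, phi, n_cycles, seed)),
            class = c("trajectory", "data.frame"),
            amplitude = spec$amplitude,
            nominal_frequency = spec$nominal_frequency)
}

#' Write / read a trajectory as CSV
#'
#' Columns `time_s,fast_angle_rad,slow_angle_rad`, header line, LF endings.
#' @param x a `trajectory` (any data frame with those columns).
#' @param path file path.
#' @export
write_trajectory_csv <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("time_s,fast_angle_rad,slow_angle_rad",
               sprintf("%.17g,%.17g,%.17g",
                       x$time_s, x$fast_angle_rad, x$slow_angle_rad)),
             con, sep = "\n")
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_s", "fast_angle_rad", "slow_angle_rad") %in% names(df)))
  structure(df, class = c("trajectory", "data.frame"))
}

#' Generate position-feedback edges
#'
#' Produces the exact turnaround times of the mirror (including drift and
#' mirror jitter) and the noisy electronic position-feedback edge series
#' derived from them: white per-edge timing noise plus optional narrowband
#' sinusoidal components, per the scanner's [feedback_noise_spec()].  The
#' feedback rising edge marks the -Theta turnaround (see package docs for
#' the cycle-origin convention).
#'
#' @param spec a [scanner_spec()].
#' @param duration simulated wall time in seconds; must cover at least two
#'   scan cycles.
#' @param seed integer run seed.
#' @return list with elements `feedback` and `true_turnarounds`, both
#'   [edge_series()] with one edge per cycle.
#' @export
generate_feedback_edges <- function(spec, duration, seed = 1L) {
  f <- spec$nominal_frequency
  n <- floor(duration * f - TURNAROUND_PHASE)
  if (n < 2L) stop("generate_feedback_edges: duration must cover at least 2 cycles")
  skel <- cycle_skeleton(spec, n, seed)
  fb <- feedback_times_from_skeleton(spec, skel, seed)
  list(feedback = edge_series(fb, skel$T0, "feedback"),
       true_turnarounds = edge_series(skel$turnaround_true, skel$T0, "optical"))
}

#' Relative jitter between two edge series
#'
#' Pairs edges by index, removes the mean of the per-cycle differences (a
#' fixed propagation delay between two clocks is not jitter), and reports
#' RMS and maximum absolute deviation.
#'
#' @param a,b [edge_series()] objects with equal edge counts.
#' @return a [jitter_report()] in seconds.
#' @export
relative_edge_jitter <- function(a, b) {
  if (length(a$timestamps) != length(b$timestamps)) {
    stop("relative_edge_jitter: edge counts differ (", length(a$timestamps),
         " vs ", length(b$timestamps), ")")
  }
  jitter_report(a$timestamps - b$timestamps, units = "s",
                label = paste0(a$label, " - ", b$label))
}
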