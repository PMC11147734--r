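#' Sampling-clock and line-trigger configuration
#'
#' `clock_spec` describes the pixel sampling clock: either `pll_locked`
#' (synthesized by subdividing the PLL's denoised x1 line clock, so sampling
#' stays phase-locked to the scanner) or `free_running` (a fixed-rate clock
#' with arbitrary phase relative to the line trigger, as when sampling
#' synchronously to a mode-locked laser).  `free_run_offset` detunes the
#' free clock from the exact integer multiple of the line rate; the default
#' 7.3 Hz makes beat behavior visible in short runs.  `trigger_config`
#' selects the line trigger source and fixes the number of samples assigned
#' to each scan cycle (S/2 forward + S/2 backward).
#'
#' @param mode `"pll_locked"` or `"free_running"`.
#' @param nominal_rate sampling rate in Hz (e.g. `80.4e6` for 12 kHz x 6700).
#' @param free_run_offset detuning in Hz of the free-running clock.
#' @param jitter_rms additive white per-edge clock jitter in seconds.
#' @param phase initial phase of the free-running clock as a fraction of
#'   one sample period in `[0, 1)`; `NULL` (the default) draws it uniformly
#'   at random per run, the generic unsynchronized case.
#' @return `clock_spec` / `trigger_config` object.
#' @export
clock_spec <- function(mode = c("pll_locked", "free_running"),
                       nominal_rate, free_run_offset = 7.3, jitter_rms = 0,
                       phase = NULL) {
  mode <- match.arg(mode)
  stopifnot(nominal_rate > 0, jitter_rms >= 0,
            is.null(phase) || (phase >= 0 && phase < 1))
  structure(list(mode = mode, nominal_rate = nominal_rate,
                 free_run_offset = free_run_offset, jitter_rms = jitter_rms,
                 phase = phase),
            class = "clock_spec")
}

#' @rdname clock_spec
#' @param source `"position_feedback"` or `"pll_x1"`.
#' @param samples_per_cycle even integer S; each sweep gets exactly S/2
#'   samples.
#' @export
trigger_config <- function(source = c("position_feedback", "pll_x1"),
                           samples_per_cycle) {
  source <- match.arg(source)
  S <- as.integer(samples_per_cycle)
  if (S < 4L || S %% 2L != 0L) {
    stop("trigger_config: samples_per_cycle must be an even integer >= 4")
  }
  structure(list(source = source, samples_per_cycle = S),
            class = "trigger_config")
}

#' Acquire line-scan records of a phantom
#'
#' Simulates the full line-scan acquisition chain: scanner cycles (drift +
#' mirror jitter), noisy feedback edges, optional PLL locking, the chosen
#' line trigger and sampling clock, and photon detection.  For each cycle
#' the line's first sample falls on the first clock edge at or after the
#' trigger edge (ties go to the current edge), so the bounded
#' +/-0.5-sample synchronization jitter and the off-by-one trigger effect
#' emerge naturally rather than being injected.  A fixed count of S
#' consecutive samples is then filled with the phantom intensity at the true
#' mirror angle at each sample time, with Poisson photon noise.
#'
#' @param spec a [scanner_spec()].
#' @param trigger a [trigger_config()].
#' @param clock a [clock_spec()]; `nominal_rate` must be within 5% of
#'   `samples_per_cycle * nominal_frequency`.
#' @param phantom a [phantom_slit()] or [phantom_powder()].
#' @param n_cycles number of recorded scan cycles (after PLL settling).
#' @param seed integer run seed.
#' @param pll [pll_config()] used when either the trigger or the clock is
#'   PLL-derived.
#' @param injected_shift_samples optional scalar or length-`n_cycles` vector
#'   of per-cycle line shifts in sample units: a controlled-jitter injection
#'   hook that delays the mirror trajectory of cycle c by
#'   `shift[c] / nominal_rate`, so the cycle's forward-sweep image moves
#'   `+shift[c]` samples and its backward-sweep image `-shift[c]` samples
#'   (the fixed-samples-per-sweep bookkeeping behind the bidirectional
#'   twice relation).
#' @param injected_trigger_jitter_samples optional scalar or per-cycle
#'   vector of trigger-time shifts in sample units, added to the trigger
#'   edge times themselves; unlike `injected_shift_samples` this moves the
#'   trigger relative to the clock edge grid and so exercises the
#'   quantization (off-by-one) mechanism.
#' @param photon_noise logical; `FALSE` records expected counts.
#' @return object of class `line_scan_record`: fields `counts`
#'   (`n_cycles x S` matrix), `trigger_times`, `quant_error_samples` (ground
#'   truth trigger-to-sample quantization error, samples), `template`
#'   (noiseless expected line at nominal sample phases), `S`, `sample_rate`,
#'   `line_rate`, `amplitude`, `phantom`, `provenance`.
#' @export
acquire_line_scan <- function(spec, trigger, clock, phantom, n_cycles,
                              seed = 1L,
                              pll = pll_config(loop_bandwidth = 100,
                                               damping = 0.7,
                                               multipliers = 1L),
                              injected_shift_samples = NULL,
                              injected_trigger_jitter_samples = NULL,
                              photon_noise = TRUE) {
  S <- trigger$samples_per_cycle
  f <- spec$nominal_frequency
  rate_nom <- clock$nominal_rate
  if (rate_nom / f < S) {
    stop("acquire_line_scan: sampling clock too slow to supply ", S,
         " samples per scan cycle")
  }
  if (abs(rate_nom - S * f) > 0.05 * S * f) {
    stop("acquire_line_scan: inconsistent rates: nominal_rate should be close to samples_per_cycle * line rate")
  }
  need_pll <- trigger$source == "pll_x1" || clock$mode == "pll_locked"
  settle <- if (need_pll) pll_settle_edges(pll, f) else 0L
  n_total <- n_cycles + settle + 14L
  skel <- cycle_skeleton(spec, n_total, seed)
  fb_times <- feedback_times_from_skeleton(spec, skel, seed)
  fb <- edge_series(fb_times, skel$T0, "feedback")

  x1 <- NULL
  if (need_pll) {
    cfg1 <- pll
    cfg1$multipliers <- 1L  # xN is subdivided lazily below
    x1 <- pll_lock(fb, cfg1)$clocks[[1L]]$timestamps
  }

  ## trigger edges: skip one extra cycle so that feedback triggers always
  ## fall inside the retained x1 clock span
  first <- settle + 2L
  g <- switch(trigger$source,
              position_feedback = fb_times[first:(first + n_cycles - 1L)],
              pll_x1 = x1[2L:(n_cycles + 1L)])
  shift <- if (is.null(injected_shift_samples)) numeric(n_cycles) else
    rep_len(as.numeric(injected_shift_samples), n_cycles)
  if (!is.null(injected_trigger_jitter_samples)) {
    g <- g + rep_len(as.numeric(injected_trigger_jitter_samples), n_cycles) / rate_nom
  }

  if (clock$mode == "free_running") {
    rate <- rate_nom + clock$free_run_offset
    phi0 <- if (is.null(clock$phase)) {
      with_substream(seed, "clock_phase", stats::runif(1L)) / rate
    } else clock$phase / rate
    x <- (g - phi0) * rate
    m0 <- ceiling(x - 1e-9)
    err <- m0 - x
    tmat <- phi0 + (outer(m0, 0:(S - 1L), "+")) / rate
  } else {
    N <- round(rate_nom / f)
    j <- findInterval(g, x1)
    if (any(j < 1L) || any(j + ceiling(S / N) + 1L > length(x1))) {
      stop("acquire_line_scan: trigger edges fall outside the locked clock span")
    }
    sub <- (x1[j + 1L] - x1[j]) / N
    frac0 <- (g - x1[j]) / sub
    k0 <- ceiling(frac0 - 1e-9)
    err <- k0 - frac0
    k <- outer(k0, 0:(S - 1L), "+")
    q <- k %/% N
    jj <- j + q  # recycles j down columns; q has matching layout
    tmat <- x1[jj] + ((k %% N) / N) * (x1[jj + 1L] - x1[jj])
  }
  if (clock$jitter_rms > 0) {
    tmat <- tmat + with_substream(seed, "clock_jitter",
                                  stats::rnorm(length(tmat), 0, clock$jitter_rms))
  }

  phantom <- realize_phantom(phantom, spec$amplitude, seed)
  ## injected line shift: evaluate the trajectory as if the mirror ran
  ## shift[c] samples late on cycle c (fractional-image-shift injection)
  teval <- if (any(shift != 0)) tmat - shift / rate_nom else tmat
  phi <- phase_at(skel, as.vector(teval))
  lambda <- phantom_expected(phantom, spec$amplitude * sin(2 * pi * phi))
  counts <- if (photon_noise) {
    with_substream(seed, "photons", stats::rpois(length(lambda), lambda))
  } else lambda
  counts <- matrix(counts, nrow = n_cycles, ncol = S)

  s_idx <- 0:(S - 1L)
  template <- phantom_expected(phantom,
                               -spec$amplitude * cos(2 * pi * s_idx / S))

  structure(list(counts = counts,
                 trigger_times = g,
                 quant_error_samples = err,
                 injected_shift_samples = shift,
                 template = template,
                 S = S,
                 sample_rate = rate_nom,
                 line_rate = f,
                 amplitude = spec$amplitude,
                 phantom = phantom,
                 provenance = list(trigger_source = trigger$source,
                                   clock_mode = clock$mode,
                                   free_run_offset = clock$free_run_offset,
                                   seed = seed, n_cycles = n_cycles,
                                   settle_cycles = settle)),
            class = "line_scan_record")
}

#' @export
print.line_scan_record <- function(x, ...) {
  cat(sprintf("<line_scan_record>: %d cycles x %d samples, trigger=%s, clock=%s, phantom=%s\n",
              nrow(x$counts), x$S, x$provenance$trigger_source,
              x$provenance$clock_mode, x$phantom$kind))
  invisible(x)
}

#' Acquire single-sweep camera frames of a pulsed laser
#'
#' Emulates placing a camera at the scan-lens focal plane while a pulsed
#' laser (period `pulse_period`, phase-locked to the scan cycle as if
#' triggered by the PLL xN clock) is scanned across it.  Each frame captures
#' exactly one forward-backward sweep: every pulse is recorded as a ground
#' truth (fast, slow, time) triple and rendered as a Gaussian spot into
#' separate forward- and backward-sweep images over a window around scan
#' center, with optional Poisson noise.  The frame rate must divide the scan
#' frequency into an integer number of cycles per frame.
#'
#' @param spec a [scanner_spec()].
#' @param pulse_period laser pulse period in seconds (100 ns for 10 MHz).
#' @param n_frames number of frames.
#' @param frame_rate frames per second (e.g. 8).
#' @param seed integer run seed.
#' @param psf_sigma rendered spot sigma in radians.
#' @param pixel_pitch camera pixel pitch in radians per pixel; the default
#'   `psf_sigma / 8` keeps subpixel localization error well below the
#'   simulated jitter.
#' @param fov_fast,fov_slow rendered half-ranges (radians) around scan
#'   center; pulses outside are kept in the ground truth but not rendered.
#' @param photon_scale expected peak counts per pulse spot.
#' @param background expected background counts per pixel.
#' @param photon_noise logical.
#' @param injected_frame_time_jitter_rms optional RMS (seconds) of a rigid
#'   per-frame timing offset between the pulse clock and the mirror
#'   trajectory -- a controlled injection hook; at scan center it converts
#'   to angle as `tau * Theta * 2 pi * f`.
#' @return list of `camera_frame` objects, each with `image_forward`,
#'   `image_backward` (matrices, rows = slow axis), `fast_axis`,
#'   `slow_axis` (pixel-center angles), `pixel_pitch`, `pulses`
#'   (ground-truth data frame), `cycle_index`.
#' @export
acquire_camera_frames <- function(spec, pulse_period = 100e-9, n_frames,
                                  frame_rate = 8, seed = 1L,
                                  psf_sigma = 100e-6,
                                  pixel_pitch = psf_sigma / 8,
                                  fov_fast = 2000e-6, fov_slow = 1000e-6,
                                  photon_scale = 1000, background = 2,
                                  photon_noise = TRUE,
                                  injected_frame_time_jitter_rms = 0) {
  f <- spec$nominal_frequency
  cpf <- f / frame_rate
  if (abs(cpf - round(cpf)) > 1e-9) {
    stop("acquire_camera_frames: frame rate must correspond to an integer number of scan cycles per frame")
  }
  cpf <- round(cpf)
  ## angular pulse spacing at scan center must be resolvable
  if (spec$amplitude * 2 * pi * f * pulse_period < 2 * pixel_pitch) {
    stop("acquire_camera_frames: pulse period below twice the render resolution")
  }
  n_total <- n_frames * cpf + 2L
  skel <- cycle_skeleton(spec, n_total, seed)
  fast_axis <- seq(-fov_fast, fov_fast, by = pixel_pitch)
  slow_axis <- seq(-fov_slow, fov_slow, by = pixel_pitch)

  render <- function(px, py, amp) {
    img <- matrix(0, nrow = length(slow_axis), ncol = length(fast_axis))
    for (i in seq_along(px)) {
      gx <- exp(-(fast_axis - px[i])^2 / (2 * psf_sigma^2))
      gy <- exp(-(slow_axis - py[i])^2 / (2 * psf_sigma^2))
      img <- img + amp * outer(gy, gx)
    }
    img + background
  }

  frame_tau <- if (injected_frame_time_jitter_rms > 0) {
    with_substream(seed, "frame_jitter",
                   stats::rnorm(n_frames, 0, injected_frame_time_jitter_rms))
  } else numeric(n_frames)
  frames <- vector("list", n_frames)
  for (fr in seq_len(n_frames)) {
    k <- (fr - 1L) * cpf + 1L
    ## pulse grid anchored to the drift-only timeline: the pulsed laser is
    ## clocked by the PLL, which averages many cycles and so does not follow
    ## per-cycle mirror jitter
    u0 <- skel$turnaround_base[k]
    u1 <- skel$turnaround_base[k + 1L]
    m <- 0:(floor((u1 - u0) / pulse_period + 1e-9) - 1L)
    tp <- u0 + m * pulse_period
    phi <- phase_at(skel, tp - frame_tau[fr])
    fast <- spec$amplitude * sin(2 * pi * phi)
    slow <- slow_angle_at(spec, phi, n_total, seed)
    fracp <- phi - floor(phi)
    forward <- fracp >= TURNAROUND_PHASE | fracp < TURNAROUND_PHASE - 0.5
    in_fov <- abs(fast) <= fov_fast + 4 * psf_sigma &
      abs(slow) <= fov_slow + 4 * psf_sigma
    img_f <- render(fast[forward & in_fov], slow[forward & in_fov], photon_scale)
    img_b <- render(fast[!forward & in_fov], slow[!forward & in_fov], photon_scale)
    if (photon_noise) {
      imgs <- with_substream(seed, paste0("camera_photons_", fr), {
        list(f = matrix(stats::rpois(length(img_f), img_f), nrow = nrow(img_f)),
             b = matrix(stats::rpois(length(img_b), img_b), nrow = nrow(img_b)))
      })
      img_f <- imgs$f; img_b <- imgs$b
    }
    frames[[fr]] <- structure(
      list(image_forward = img_f, image_backward = img_b,
           fast_axis = fast_axis, slow_axis = slow_axis,
           pixel_pitch = pixel_pitch,
           pulses = data.frame(time_s = tp, fast_angle_rad = fast,
                               slow_angle_rad = slow, forward = forward,
                               in_fov = in_fov),
           cycle_index = k, frame_index = fr),
      class = "camera_frame")
  }
  frames
}

#' Sinusoidal dewarp map
#'
#' Maps the S/2 uniformly clocked samples of each sweep onto `n_pixels`
#' uniform angular pixels.  Forward-sweep sample `s` (0-based, `s < S/2`)
#' sits at angle `-Theta * cos(2 pi s / S)` and maps to pixel coordinate
#' `p = n_pixels * (angle + Theta) / (2 Theta)`; the backward map is its
#' mirror image.
#'
#' @param S even samples per cycle.
#' @param n_pixels pixels per dewarped line (e.g. 2048).
#' @param amplitude optical half-angle Theta in radians.
#' @return object of class `dewarp_map` with per-sweep pixel coordinates.
#' @export
build_dewarp_map <- function(S, n_pixels, amplitude) {
  S <- as.integer(S)
  stopifnot(S %% 2L == 0L, n_pixels >= 2L, amplitude > 0)
  s_f <- 0:(S %/% 2L - 1L)
  s_b <- (S %/% 2L):(S - 1L)
  pixel_of <- function(s) n_pixels * (1 - cos(2 * pi * s / S)) / 2
  structure(list(forward_pixel = pixel_of(s_f),
                 backward_pixel = pixel_of(s_b),
                 pixel_of = pixel_of,
                 S = S, n_pixels = as.integer(n_pixels),
                 amplitude = amplitude),
            class = "dewarp_map")
}

## Mean-preserving rebin: v holds means over cells bounded by xb (len(v)+1,
## monotone increasing); returns means over cells bounded by new_edges.
## Degenerate target cells (outside the source span) inherit their nearest
## neighbour's value.
rebin_mean <- function(xb, v, new_edges) {
  K <- c(0, cumsum(v * diff(xb)))
  Kn <- stats::approx(xb, K, xout = pmin(pmax(new_edges, xb[1L]), xb[length(xb)]),
                      ties = "ordered")$y
  wn <- diff(pmin(pmax(new_edges, xb[1L]), xb[length(xb)]))
  out <- diff(Kn) / ifelse(wn > 1e-12 * mean(diff(xb)), wn, NA)
  if (anyNA(out)) {
    ok <- which(!is.na(out))
    if (!length(ok)) stop("rebin_mean: target grid does not overlap the source span")
    out <- stats::approx(ok, out[ok], xout = seq_along(out), rule = 2)$y
  }
  out
}

#' Dewarp line-scan samples to uniform pixels
#'
#' Interval-averaged (mean-preserving) resampling of each sweep onto the
#' uniform pixel grid of a [build_dewarp_map()]: the cumulative intensity is
#' interpolated at the pixel-cell boundaries mapped through the sinusoidal
#' map, so a flat field stays flat and total intensity (counts x dwell) is
#' conserved.  `dewarp_invert()` resamples a pixel-domain line back onto the
#' sample grid, the approximate inverse used for round-trip checks.
#'
#' @param record a `line_scan_record`, or a numeric vector of length S.
#' @param map a [build_dewarp_map()] with matching S.
#' @return list with `forward` and `backward` matrices
#'   (`n_cycles x n_pixels`); for a single line, numeric vectors.
#' @export
dewarp_line <- function(record, map) {
  lines <- if (inherits(record, "line_scan_record")) record$counts else
    matrix(record, nrow = 1L)
  if (ncol(lines) != map$S) {
    stop("dewarp_line: record has ", ncol(lines), " samples per cycle but map expects ", map$S)
  }
  S2 <- map$S %/% 2L
  edges <- 0:map$n_pixels
  pb_f <- map$pixel_of(seq(-0.5, S2 - 0.5, by = 1))
  pb_b <- map$pixel_of(seq(S2 - 0.5, map$S - 0.5, by = 1))
  fw <- t(apply(lines[, 1:S2, drop = FALSE], 1L,
                function(v) rebin_mean(pb_f, v, edges)))
  ## backward boundaries run from n_pixels down to 0; reverse sample order
  ## so both sweeps land on the same increasing pixel axis
  bw <- t(apply(lines[, (S2 + 1L):map$S, drop = FALSE], 1L,
                function(v) rebin_mean(rev(pb_b), rev(v), edges)))
  if (!inherits(record, "line_scan_record")) {
    list(forward = fw[1L, ], backward = bw[1L, ])
  } else list(forward = fw, backward = bw)
}

#' @rdname dewarp_line
#' @param pixels numeric vector of length `n_pixels` (a forward-sweep
#'   pixel-domain line).
#' @export
dewarp_invert <- function(pixels, map) {
  S2 <- map$S %/% 2L
  pb_f <- map$pixel_of(seq(-0.5, S2 - 0.5, by = 1))
  rebin_mean(0:map$n_pixels, pixels, pb_f)
}

#' Beat frequency of an unsynchronized sampling clock
#'
#' A free-running sampling clock cannot hold an exact integer-multiple
#' relationship to the line rate; the residual detune mixes down, when
#' sampled once per line, to `|rate - round(rate / line_rate) * line_rate|`
#' aliased into `[0, line_rate / 2]`.  A PLL-locked clock has no beat.
#'
#' @param clock a [clock_spec()].
#' @param line_rate line (scan-cycle) rate in Hz.
#' @return beat frequency in Hz.
#' @export
predict_beat_frequency <- function(clock, line_rate) {
  if (clock$mode == "pll_locked") return(0)
  rate <- clock$nominal_rate + clock$free_run_offset
  b <- abs(rate - round(rate / line_rate) * line_rate)
  b <- b %% line_rate
  if (b > line_rate / 2) b <- line_rate - b
  b
}
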