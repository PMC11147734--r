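test_that("fully synchronous acquisition has no synchronization jitter", {
  rec <- acquire_line_scan(quiet_spec_12k(), fix_trigger("pll_x1"),
                           fix_clock_pll(), fix_slit(), n_cycles = 100,
                           seed = 3, photon_noise = FALSE)
  expect_lt(rms_centered(rec$quant_error_samples), 1e-9)
  centers <- slit_center_series(rec)
  expect_lt(centers$rms, 1e-9)
})

test_that("free-running clock gives bounded uniform quantization error", {
  # 10,000 lines cover ~6 beat periods of the 7.3 Hz detune, enough for the
  # swept trigger-clock phase to fill [0, 1) nearly uniformly
  rec <- acquire_line_scan(quiet_spec_12k(), fix_trigger("pll_x1"),
                           fix_clock_free(offset = 7.3), fix_slit(),
                           n_cycles = 10000, seed = 8, photon_noise = FALSE)
  e <- rec$quant_error_samples
  expect_gte(min(e), 0)
  expect_lt(max(e), 1)
  expect_lt(max(abs(e - 0.5)), 0.5 + 1e-12)
  expect_equal(rms_centered(e), 1 / sqrt(12), tolerance = 0.03)
  # uniformity: quartiles near 0.25/0.5/0.75
  expect_lt(max(abs(quantile(e, c(.25, .5, .75)) - c(.25, .5, .75))), 0.04)
})

test_that("an exact per-cycle shift moves the two sweeps in opposite directions", {
  base <- acquire_line_scan(quiet_spec_12k(), fix_trigger("pll_x1"),
                            fix_clock_pll(), fix_slit(), 4, seed = 6,
                            photon_noise = FALSE)
  shifted <- acquire_line_scan(quiet_spec_12k(), fix_trigger("pll_x1"),
                               fix_clock_pll(), fix_slit(), 4, seed = 6,
                               photon_noise = FALSE,
                               injected_shift_samples = c(0, 0.7, 0, 0))
  S2 <- FIX_S / 2
  fw_b <- locate_peak_subsample(base$counts[2, 1:S2])
  fw_s <- locate_peak_subsample(shifted$counts[2, 1:S2])
  expect_equal(fw_s - fw_b, 0.7, tolerance = 0.01)
  bw_b <- locate_peak_subsample(rev(base$counts[2, (S2 + 1):FIX_S]))
  bw_s <- locate_peak_subsample(rev(shifted$counts[2, (S2 + 1):FIX_S]))
  expect_equal(bw_s - bw_b, -0.7, tolerance = 0.01)
  # untouched cycles identical
  expect_identical(shifted$counts[1, ], base$counts[1, ])
})

test_that("acquisition rejects inconsistent clocking", {
  expect_error(acquire_line_scan(quiet_spec_12k(), fix_trigger(),
                                 clock_spec("pll_locked", FIX_RATE / 3),
                                 fix_slit(), 10, seed = 1),
               "too slow")
  expect_error(acquire_line_scan(quiet_spec_12k(), fix_trigger(),
                                 clock_spec("pll_locked", FIX_RATE * 1.07),
                                 fix_slit(), 10, seed = 1),
               "inconsistent rates")
  expect_error(trigger_config("pll_x1", 15), "even integer")
})

test_that("photon counting is Poisson at the per-sample level", {
  rec <- acquire_line_scan(quiet_spec_12k(), fix_trigger("pll_x1"),
                           fix_clock_pll(), fix_slit_wide(photon_scale = 500),
                           n_cycles = 600, seed = 12)
  # background samples far from the slit: mean should equal variance
  bgcols <- 5:20
  vals <- as.vector(rec$counts[, bgcols])
  expect_equal(var(vals), mean(vals), tolerance = 0.05)
  # bright samples too
  peak <- rec$counts[, which.max(rec$template)]
  expect_equal(var(peak), mean(peak), tolerance = 0.15)
})

test_that("camera frames carry the right pulse census and determinism", {
  spec8 <- scanner_spec(8000)
  frames <- acquire_camera_frames(spec8, pulse_period = 100e-9, n_frames = 2,
                                  frame_rate = 8, seed = 2,
                                  photon_noise = FALSE)
  expect_identical(nrow(frames[[1]]$pulses), 1250L)  # 10 MHz at 8 kHz
  expect_equal(sum(frames[[1]]$pulses$forward), 625L)
  # wobble off: everything on the fast axis
  expect_lt(max(abs(frames[[1]]$pulses$slow_angle_rad)), 1e-12)
  # deterministic wobble: identical pulse positions at identical phase
  specw <- scanner_spec(12000, amplitude = 0.08727,
                        wobble = wobble_spec(ellipse_semi_minor = 200e-6,
                                             hf_oscillation_amplitude = 5e-6))
  fw <- acquire_camera_frames(specw, 100e-9, n_frames = 2, frame_rate = 4000,
                              seed = 4, photon_noise = FALSE)
  expect_equal(fw[[2]]$pulses$slow_angle_rad, fw[[1]]$pulses$slow_angle_rad,
               tolerance = 1e-12)
  expect_error(acquire_camera_frames(spec8, 100e-9, 2, frame_rate = 7, seed = 1),
               "integer number of scan cycles")
  expect_error(acquire_camera_frames(spec8, 1e-10, 2, frame_rate = 8, seed = 1),
               "render resolution")
})

test_that("dewarp map satisfies its anchor points and geometry", {
  map <- build_dewarp_map(6700, 2048, 0.08727)
  expect_identical(length(map$forward_pixel), 3350L)
  expect_identical(length(map$backward_pixel), 3350L)
  expect_equal(map$forward_pixel[1], 0)
  expect_equal(map$pixel_of(6700 / 4), 1024)
  expect_true(all(diff(map$forward_pixel) > 0))
  expect_true(all(diff(map$backward_pixel) < 0))
})

test_that("dewarping preserves flat fields, widths and totals", {
  S <- 2000L
  np <- 512L
  map <- build_dewarp_map(S, np, 0.1)
  flat <- dewarp_line(rep(7, S), map)
  expect_equal(range(flat$forward), c(7, 7))
  expect_equal(range(flat$backward), c(7, 7))
  rps <- 0.1 * 2 * pi / S
  v <- phantom_expected(phantom_slit(0, 24 * rps, 8 * rps, 1000, 0),
                        -0.1 * cos(2 * pi * (0:(S - 1)) / S))
  dw <- dewarp_line(v, map)
  # local-derivative width scaling at scan center
  expect_equal(fwhm(dw$forward) / fwhm(v[1:(S / 2)]), pi * np / S,
               tolerance = 0.01)
  # totals: pixel-domain intensity times sample-per-pixel width
  pb <- map$pixel_of(seq(-0.5, S / 2 - 0.5, by = 1))
  widths <- diff(stats::approx(pb, seq(-0.5, S / 2 - 0.5, by = 1),
                               xout = pmin(pmax(0:np, pb[1]), max(pb)),
                               ties = "ordered")$y)
  expect_equal(sum(dw$forward * widths), sum(v[1:(S / 2)]), tolerance = 1e-3)
  # both sweeps sample the same static profile on their own lattices, so
  # their dewarped lines must agree on the common pixel axis
  dwm <- dewarp_line(v, map)
  core_px <- 30:(np - 30)
  expect_lt(max(abs(dwm$backward[core_px] - dwm$forward[core_px])) / max(v),
            0.01)
  # round trip through the inverse map
  smooth <- 500 + 300 * sin(2 * pi * (0:(S / 2 - 1)) / 250)
  rt <- dewarp_invert(dewarp_line(c(smooth, rev(smooth)), map)$forward, map)
  core <- 100:(S / 2 - 100)
  expect_lt(max(abs(rt[core] - smooth[core])) / 500, 0.05)
  expect_error(dewarp_line(rep(1, S + 2), map), "samples per cycle")
})

test_that("beat frequency prediction matches residues and a DFT oracle", {
  expect_equal(predict_beat_frequency(fix_clock_free(offset = 10), FIX_F12), 10)
  expect_equal(predict_beat_frequency(fix_clock_free(offset = 0), FIX_F12), 0)
  expect_equal(predict_beat_frequency(fix_clock_pll(), FIX_F12), 0)
  # detune near the line rate folds: 11.9 kHz detune at 12 kHz -> 100 Hz
  expect_equal(predict_beat_frequency(fix_clock_free(offset = 11900), FIX_F12),
               100)
  # brute-force DFT oracle on the per-line clock phase series
  for (detune in c(10, 11900)) {
    rate <- FIX_RATE + detune
    n <- 6000
    ph <- ((seq_len(n) - 1) / FIX_F12 * rate) %% 1
    ph <- ph - mean(ph)
    spec_p <- Mod(stats::fft(ph))[2:(n / 2)]
    peak_hz <- (which.max(spec_p)) * FIX_F12 / n
    expect_equal(peak_hz,
                 predict_beat_frequency(fix_clock_free(offset = detune), FIX_F12),
                 tolerance = FIX_F12 / n / 5)
  }
})
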