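test_that("slit-center series recovers injected shift statistics", {
  # constant shift: mean removal leaves nothing
  rec_const <- acquire_line_scan(quiet_spec_12k(), fix_trigger("pll_x1"),
                                 fix_clock_pll(), fix_slit(), 50, seed = 14,
                                 photon_noise = FALSE,
                                 injected_shift_samples = 0.4)
  expect_lt(slit_center_series(rec_const)$rms, 1e-6)
  # Gaussian shifts are recovered
  set.seed(41)
  shifts <- rnorm(2500, 0, 0.324)
  rec <- acquire_line_scan(quiet_spec_12k(), fix_trigger("pll_x1"),
                           fix_clock_pll(), fix_slit(photon_scale = 10000),
                           2500, seed = 15, injected_shift_samples = shifts)
  sc <- slit_center_series(rec)
  expect_equal(sc$rms, rms_centered(shifts), tolerance = 0.03)
  expect_identical(sc$n + sc$n_excluded, 2500L)
})

test_that("misalignment is zero for identical mirrored sweeps, antisymmetric on swap", {
  v <- 10 + 500 * exp(-((0:99) - 42.3)^2 / 8)
  rec <- synthetic_record(rbind(c(v, rev(v)), c(v, rev(v))))
  bd <- bidirectional_misalignment(rec)
  expect_equal(bd$delta_d, c(0, 0), tolerance = 1e-10)
  # antisymmetry under forward/backward exchange, on structured data
  set.seed(77)
  w <- 10 + 400 * exp(-outer(0:99, c(23.4, 61.2), "-")^2 / 10) %*% c(1, 0.7)
  wb <- rev(10 + 400 * exp(-outer(0:99, c(25.1, 63.0), "-")^2 / 10) %*% c(1, 0.7))
  rec_ab <- synthetic_record(matrix(c(w, wb), nrow = 1))
  rec_ba <- synthetic_record(matrix(c(rev(wb), rev(w)), nrow = 1))
  d1 <- bidirectional_misalignment(rec_ab)$delta_d
  d2 <- bidirectional_misalignment(rec_ba)$delta_d
  expect_equal(d1, -d2, tolerance = 1e-9)
})

test_that("injected line shifts obey the twice relation", {
  base <- acquire_line_scan(quiet_spec_12k(), fix_trigger("pll_x1"),
                            fix_clock_pll(), fix_slit(photon_scale = 10000),
                            40, seed = 16, injected_shift_samples = 0)
  d0 <- mean(bidirectional_misalignment(base)$delta_d)
  one <- acquire_line_scan(quiet_spec_12k(), fix_trigger("pll_x1"),
                           fix_clock_pll(), fix_slit(photon_scale = 10000),
                           40, seed = 16, injected_shift_samples = 0.7)
  d1 <- mean(bidirectional_misalignment(one)$delta_d)
  expect_equal(d1 - d0, 1.4, tolerance = 0.05 / 1.4)
  # regression of delta_d on known shifts, powder phantom at modest SNR
  shifts <- rep(seq(0.1, 2.0, by = 0.1), each = 25)
  recp <- acquire_line_scan(quiet_spec_12k(), fix_trigger("pll_x1"),
                            fix_clock_pll(), fix_powder(photon_scale = 100),
                            length(shifts), seed = 18,
                            injected_shift_samples = shifts)
  bd <- bidirectional_misalignment(recp)
  ok <- !bd$flagged
  slope <- coef(lm(bd$delta_d[ok] ~ shifts[ok]))[[2]]
  expect_equal(slope, 2, tolerance = 0.01)
})

test_that("welch psd satisfies parseval, finds tones, and needs enough data", {
  set.seed(19)
  x <- rnorm(5000, 0, 3)
  p <- jitter_psd(jitter_report(x, "samples"), event_rate = 12000)
  expect_equal(sum(p$power) * diff(p$frequencies[1:2]), var(x),
               tolerance = 0.05)
  t <- (0:4095) / 1000
  tone <- jitter_report(0.3 * sin(2 * pi * 57 * t), "s")
  pt <- jitter_psd(tone, 1000, segment_length = 1024)
  pk <- pt$frequencies[which.max(pt$power)]
  expect_lt(abs(pk - 57), 1000 / 1024)
  expect_error(jitter_psd(jitter_report(rnorm(100), "s"), 1000), "at least 256")
})

test_that("narrowband feedback noise is attenuated by the squared loop gain", {
  f0 <- 150
  spec <- scanner_spec(12000, amplitude = 0.08727,
                       feedback_noise = feedback_noise_spec(
                         white_rms = 0.2e-9,
                         band_components = list(c(f0, 3e-9))))
  cfg <- pll_config(100, 0.7, multipliers = 1L)
  n <- scanlock:::pll_settle_edges(cfg, 12000) + 8192L
  edges <- generate_feedback_edges(spec, (n + 2) / 12000, seed = 21)
  lock <- pll_lock(edges$feedback, cfg)
  keep <- (lock$settle_edges + 1L):length(edges$feedback$timestamps)
  tr <- edge_series(edges$true_turnarounds$timestamps[keep], 1 / 12000, "opt")
  rep_in <- relative_edge_jitter(
    edge_series(edges$feedback$timestamps[keep], 1 / 12000, "fb"), tr)
  rep_out <- relative_edge_jitter(lock$clocks[[1L]], tr)
  psd_in <- jitter_psd(rep_in, 12000, segment_length = 2048)
  psd_out <- jitter_psd(rep_out, 12000, segment_length = 2048)
  bin <- which.min(abs(psd_in$frequencies - f0))
  ratio <- psd_out$power[bin] / psd_in$power[bin]
  gain2 <- jitter_transfer(cfg, 12000, psd_in$frequencies[bin])^2
  expect_equal(ratio, gain2, tolerance = 0.2)
  # and a probe below the loop bandwidth passes essentially unattenuated
  expect_gt(jitter_transfer(cfg, 12000, 20), 0.97)
})

test_that("intra-cycle jitter sees differential but not common-mode noise", {
  set.seed(25)
  common <- rnorm(10000, 0, 5e-9)
  base_f <- (1:10000) / 12000
  expect_lt(intra_cycle_jitter(base_f + common, base_f + 4e-5 + common)$rms,
            1e-12)
  sig <- 2e-9
  a <- rnorm(10000, 0, sig)
  b <- rnorm(10000, 0, sig)
  expect_equal(intra_cycle_jitter(base_f + a, base_f + b)$rms, sqrt(2) * sig,
               tolerance = 0.03)
  # perfectly anticorrelated (mirrored) jitter partially cancels:
  # backward - forward = -2a, but mirrored ANGLE jitter means time jitter of
  # the two sweeps has opposite sign, so the separation is constant
  expect_lt(intra_cycle_jitter(base_f + a, base_f + 4e-5 - (-a))$rms,
            sqrt(2) * sig)
  expect_equal(intra_cycle_jitter(base_f + a, base_f + 4e-5 + a)$rms, 0,
               tolerance = 1e-12)
  expect_error(intra_cycle_jitter(base_f, base_f[-1]), "pairing mismatch")
})

test_that("2d pulse tracking recovers injected jitter magnitudes", {
  # per-frame fast-axis timing jitter converts via the scan-center slope
  spec <- scanner_spec(12000, amplitude = 0.08727)
  tau <- 2e-9
  frames <- acquire_camera_frames(spec, 100e-9, n_frames = 50, frame_rate = 8,
                                  seed = 26, fov_fast = 1200e-6,
                                  fov_slow = 600e-6,
                                  injected_frame_time_jitter_rms = tau)
  tk <- track_2d_pulses(frames)
  slope <- 0.08727 * 2 * pi * 12000
  realized <- rms_centered(scanlock:::with_substream(26, "frame_jitter",
                                                     rnorm(50, 0, tau)))
  fwd <- tk[tk$sweep == "forward", ]
  expect_equal(rms_centered(fwd$fast_angle_rad), realized * slope,
               tolerance = 0.03)
  # noiseless frames: constant series at the localization floor
  quiet <- acquire_camera_frames(spec, 100e-9, n_frames = 4, frame_rate = 8,
                                 seed = 27, fov_fast = 1200e-6,
                                 fov_slow = 600e-6, photon_noise = FALSE)
  tq <- track_2d_pulses(quiet)
  for (sw in c("forward", "backward")) {
    sub <- tq$fast_angle_rad[tq$sweep == sw]
    expect_lt(max(abs(sub - mean(sub))), 1e-7)
  }
})

test_that("ellipse fitting handles clean, noisy, circular and flat inputs", {
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  fit <- fit_wobble_ellipse(0.1745 * sin(th), 400e-6 * cos(th))
  expect_lt(abs(fit$semi_minor - 400e-6), 1e-12)
  expect_lt(abs(fit$semi_major - 0.1745), 1e-9)
  set.seed(30)
  fit_n <- fit_wobble_ellipse(0.1745 * sin(th),
                              400e-6 * cos(th) + rnorm(720, 0, 5e-6))
  expect_equal(fit_n$semi_minor, 400e-6, tolerance = 0.02)
  circ <- fit_wobble_ellipse(cos(th), sin(th))
  expect_equal(circ$semi_major, circ$semi_minor, tolerance = 1e-9)
  flat <- fit_wobble_ellipse(0.1 * sin(th), rep(0, 720))
  expect_true(flat$degenerate)
  expect_identical(flat$semi_minor, 0)
  expect_error(fit_wobble_ellipse(1:4, 1:4), "length")
})

test_that("percent reduction reproduces the headline arithmetic", {
  expect_equal(percent_reduction(0.324, 0.046), 85.8, tolerance = 1e-3)
  expect_identical(percent_reduction_label(0.324, 0.046), "86%")
  expect_equal(percent_reduction(3, 3), 0)
  expect_equal(percent_reduction(3, 0), 100)
  expect_error(percent_reduction(0, 1), "positive")
})
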