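test_that("noiseless edge generation is exactly periodic", {
  edges <- generate_feedback_edges(scanner_spec(8000), duration = 0.05, seed = 1)
  spacing <- diff(edges$feedback$timestamps)
  expect_lt(max(abs(spacing - 1 / 8000)), 1e-15)
  expect_identical(edges$feedback$timestamps, edges$true_turnarounds$timestamps)
})

test_that("trajectory hits the trivial phase anchors", {
  spec <- scanner_spec(12000, amplitude = 0.08727)
  tr <- simulate_trajectory(spec, c(0, 1 / (4 * 12000), 1 / (2 * 12000)), seed = 1)
  expect_equal(tr$fast_angle_rad[1], 0, tolerance = 1e-12)
  expect_equal(tr$fast_angle_rad[2], 0.08727, tolerance = 1e-12)
  expect_equal(tr$fast_angle_rad[3], 0, tolerance = 1e-10)
  expect_error(simulate_trajectory(spec, c(0, 2e-5, 1e-5), seed = 1),
               "strictly increasing")
})

test_that("elliptical wobble traces the stated ellipse", {
  spec <- scanner_spec(8000, wobble = wobble_spec(ellipse_semi_minor = 400e-6))
  tr <- simulate_trajectory(spec, seq(0, 1 / 8000, by = 100e-9), seed = 3)
  # implicit-ellipse residual with the known axes
  resid <- (tr$fast_angle_rad / spec$amplitude)^2 +
    (tr$slow_angle_rad / 400e-6)^2 - 1
  expect_lt(max(abs(resid)), 1e-12)
  fit <- fit_wobble_ellipse(tr$fast_angle_rad, tr$slow_angle_rad)
  expect_equal(fit$semi_minor, 400e-6, tolerance = 1e-9)
})

test_that("deterministic wobble is phase-locked across cycles", {
  spec <- scanner_spec(12000, amplitude = 0.08727,
                       wobble = wobble_spec(ellipse_semi_minor = 100e-6,
                                            hf_oscillation_amplitude = 5e-6,
                                            hf_oscillation_frequency = 924e3))
  t1 <- seq(0, 1 / 12000, length.out = 257)
  k <- 40
  tr1 <- simulate_trajectory(spec, t1, seed = 5)
  tr2 <- simulate_trajectory(spec, t1 + k / 12000, seed = 5)
  expect_equal(tr2$slow_angle_rad, tr1$slow_angle_rad, tolerance = 1e-12)
  expect_equal(tr2$fast_angle_rad, tr1$fast_angle_rad, tolerance = 1e-9)
})

test_that("injected white feedback jitter is recovered from the edge series", {
  spec <- scanner_spec(8000,
                       feedback_noise = feedback_noise_spec(white_rms = 3.38e-9))
  edges <- generate_feedback_edges(spec, duration = 1e5 / 8000 + 1e-3, seed = 11)
  expect_gte(length(edges$feedback$timestamps), 1e5)
  rep <- relative_edge_jitter(edges$feedback, edges$true_turnarounds)
  expect_equal(rep$rms, 3.38e-9, tolerance = 0.05)
})

test_that("degenerate drift settings reproduce the no-drift series", {
  base <- scanner_spec(8000, mirror_jitter_rms = 1e-9)
  rw0 <- scanner_spec(8000, mirror_jitter_rms = 1e-9,
                      drift = drift_model("random_walk", random_walk_step_rms = 0))
  e1 <- generate_feedback_edges(base, 0.1, seed = 9)
  e2 <- generate_feedback_edges(rw0, 0.1, seed = 9)
  expect_identical(e1$feedback$timestamps, e2$feedback$timestamps)
})

test_that("random-walk drift keeps zero long-term mean fractional frequency", {
  step <- 1e-7
  n <- 20000L
  for (seed in c(2, 12, 22)) {
    spec <- scanner_spec(8000, drift = drift_model("random_walk",
                                                   random_walk_step_rms = step))
    edges <- generate_feedback_edges(spec, (n + 2) / 8000, seed = seed)
    frac <- (1 / 8000) / diff(edges$feedback$timestamps) - 1
    expect_lt(abs(mean(frac)), 3 * step * sqrt(length(frac)))
  }
})

test_that("relative_edge_jitter matches its definition and symmetry", {
  e <- generate_feedback_edges(scanner_spec(8000), 0.02, seed = 1)$feedback
  expect_equal(relative_edge_jitter(e, e)$rms, 0)
  shifted <- edge_series(e$timestamps + 42e-9, e$nominal_period, "shifted")
  expect_lt(relative_edge_jitter(shifted, e)$rms, 1e-15)
  # Monte-Carlo concentration of the sample RMS at n = 1e5
  n <- 1e5
  base <- seq_len(n) * 1.25e-4
  set.seed(31)
  noisy <- base + rnorm(n, 0, 1e-9)
  a <- edge_series(noisy, 1.25e-4, "a")
  b <- edge_series(base, 1.25e-4, "b")
  expect_equal(relative_edge_jitter(a, b)$rms, 1e-9, tolerance = 0.02)
  expect_equal(relative_edge_jitter(a, b)$rms, relative_edge_jitter(b, a)$rms)
  expect_error(relative_edge_jitter(a, edge_series(base[-1], 1.25e-4, "c")),
               "edge counts differ")
})

test_that("edge series validation rejects malformed input", {
  expect_error(edge_series(c(0, 1e-4, 9e-5), 1e-4), "strictly increasing")
  expect_error(edge_series(c(0, 1e-4, 3.5e-4), 1e-4), "20%")
})

test_that("edge series and trajectory CSV round-trip", {
  e <- generate_feedback_edges(scanner_spec(8000,
         feedback_noise = feedback_noise_spec(white_rms = 1e-9)),
       0.01, seed = 4)$feedback
  path <- withr::local_tempfile(fileext = ".csv")
  write_edge_series_csv(e, path)
  back <- read_edge_series_csv(path)
  expect_equal(back$timestamps, e$timestamps)
  expect_equal(back$nominal_period, e$nominal_period)
  tr <- simulate_trajectory(scanner_spec(8000), seq(0, 2e-4, by = 1e-6), seed = 1)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path2)
  back2 <- read_trajectory_csv(path2)
  expect_equal(back2$fast_angle_rad, tr$fast_angle_rad)
})
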