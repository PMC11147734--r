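# ideal reference edge series at rate f with optional timing deviation
ref_edges <- function(n, f, dev = 0) {
  edge_series(((seq_len(n) - 1) / f) + dev, 1 / f, "ref")
}

test_that("clock synthesis yields the advertised output rates", {
  cfg <- pll_config(200, 0.7, multipliers = c(1L, 1250L))
  n <- scanlock:::pll_settle_edges(cfg, 8000) + 60L
  lock <- pll_lock(ref_edges(n, 8000), cfg)
  x1 <- lock$clocks[[1L]]
  xN <- lock$clocks[[2L]]
  expect_equal(mean(1 / diff(xN$timestamps)), 10e6, tolerance = 1e-9)
  # conservation: exactly N subdivisions per retained x1 period
  expect_identical(length(xN$timestamps), 1250L * (length(x1$timestamps) - 1L))
  # 12 kHz x 6700 -> 80.4 MHz
  cfg2 <- pll_config(100, 0.7, multipliers = 6700L)
  n2 <- scanlock:::pll_settle_edges(cfg2, 12000) + 40L
  hf <- pll_lock(ref_edges(n2, 12000), cfg2)$clocks[[1L]]
  expect_equal(mean(1 / diff(hf$timestamps)), 80.4e6, tolerance = 1e-9)
})

test_that("lock() agrees with a structurally different state-space oracle", {
  f <- 12000
  cfg <- pll_config(100, 0.7, multipliers = 1L)
  n <- scanlock:::pll_settle_edges(cfg, f) + 2000L
  set.seed(17)
  dev <- rnorm(n, 0, 2e-9)
  ref <- ref_edges(n, f, dev)
  x1 <- pll_lock(ref, cfg)$clocks[[1L]]$timestamps
  # oracle: same loop written as a matrix state-space recursion on the
  # deviation variables [p_dev, tau_dev]
  g <- scanlock:::pll_gains(cfg, f)
  A <- matrix(c(1 - g$kp - g$ki, 1, -g$ki, 1), 2L, byrow = TRUE)
  B <- c(g$kp + g$ki, g$ki)
  s <- c(dev[1L], 0)
  p_dev <- numeric(n)
  p_dev[1L] <- dev[1L]
  for (i in seq_len(n - 1L)) {
    s <- A %*% s + B * dev[i]
    p_dev[i + 1L] <- s[1L]
  }
  oracle <- ((seq_len(n) - 1) / f + p_dev)[(scanlock:::pll_settle_edges(cfg, f) + 1L):n]
  expect_lt(max(abs(x1 - oracle)), 1e-12)
})

test_that("jitter transfer has unit DC gain and strong stop-band attenuation", {
  cfg <- pll_config(100, 0.7)
  expect_equal(jitter_transfer(cfg, 12000, 100 / 1000), 1, tolerance = 1e-3)
  expect_gte(-20 * log10(jitter_transfer(cfg, 12000, 10 * 100)), 20)
  # monotone nonincreasing above the response peak
  fs <- seq(50, 5000, by = 25)
  gains <- jitter_transfer(cfg, 12000, fs)
  pk <- which.max(gains)
  expect_true(all(diff(gains[pk:length(gains)]) <= 1e-12))
  # drift tracking: slow modulation at BW/20 passes essentially unattenuated
  expect_gte(jitter_transfer(cfg, 12000, 5), 0.99)
  expect_error(jitter_transfer(cfg, 12000, 7000), "inside")
})

test_that("time-domain lock matches the closed-form transfer for sine probes", {
  f <- 12000
  bw <- 100
  cfg <- pll_config(bw, 0.7, multipliers = 1L)
  settle <- scanlock:::pll_settle_edges(cfg, f)
  for (fm in c(0.1 * bw, bw, 10 * bw)) {
    n <- settle + max(6000L, ceiling(8 * f / fm))
    k <- 0:(n - 1)
    A <- 2e-9
    ref <- ref_edges(n, f, A * sin(2 * pi * fm * k / f))
    x1 <- pll_lock(ref, cfg)$clocks[[1L]]$timestamps
    keep <- (settle + 1L):n
    t <- (keep - 1) / f
    cf <- coef(stats::lm(I(x1 - t) ~ sin(2 * pi * fm * t) + cos(2 * pi * fm * t)))
    measured <- sqrt(cf[[2]]^2 + cf[[3]]^2) / A
    expect_equal(measured, jitter_transfer(cfg, f, fm), tolerance = 0.01)
  }
})

test_that("white-jitter suppression equals the equivalent-noise-bandwidth ratio", {
  f <- 12000
  cfg <- pll_config(100, 0.7, multipliers = 1L)
  settle <- scanlock:::pll_settle_edges(cfg, f)
  n <- settle + 30000L
  set.seed(23)
  dev <- rnorm(n, 0, 2e-9)
  ref <- ref_edges(n, f, dev)
  x1 <- pll_lock(ref, cfg)$clocks[[1L]]$timestamps
  keep <- (settle + 1L):n
  out_var <- var(x1 - (keep - 1) / f)
  ratio <- out_var / var(dev[keep])
  expect_equal(ratio, 1 / effective_averaging_periods(cfg, f), tolerance = 0.15)
  # zero-delay: output mean tracks the reference mean
  expect_lt(abs(mean(x1 - ref$timestamps[keep])), 3 * 2e-9 / sqrt(length(keep)))
})

test_that("effective averaging periods sits in the expected band and scales", {
  val <- effective_averaging_periods(pll_config(100, 0.7), 12000)
  expect_gt(val, 35)
  expect_lt(val, 65)
  # the halving law holds in the BW << reference-rate regime; at 200 Hz on
  # a 12 kHz reference the one-update-per-edge discretization already bends
  # it by a few percent
  lo <- effective_averaging_periods(pll_config(25, 0.7), 12000)
  hi <- effective_averaging_periods(pll_config(50, 0.7), 12000)
  expect_equal(lo / hi, 2, tolerance = 0.01)
})

test_that("malformed references are rejected with the offending cycle", {
  cfg <- pll_config(100, 0.7)
  n <- scanlock:::pll_settle_edges(cfg, 12000) + 100L
  t <- (seq_len(n) - 1) / 12000
  expect_error(pll_lock(edge_series(t[1:50], 1 / 12000), cfg), "too short")
  bad <- t
  bad[2000:n] <- bad[2000:n] + 0.19 / 12000  # near-gap inside the 20% guard
  es <- edge_series(bad, 1 / 12000)
  expect_silent(pll_lock(es, cfg))
  # a real dropped edge (gap > 1.5 periods) must be rejected by cycle index
  gap <- edge_series(t, 1 / 12000)
  gap$timestamps <- t[-2000L]  # bypass the constructor: simulate corruption
  expect_error(pll_lock(gap, cfg), "1999")
})
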