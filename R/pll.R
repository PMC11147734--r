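#' Zero-delay PLL configuration
#'
#' A discrete-time type-II (proportional + integral) phase-locked loop that
#' updates once per reference edge.  The loop low-passes the reference edge
#' timing with corner `loop_bandwidth`: reference jitter above the corner is
#' attenuated while slow frequency drift below it is tracked.  Output clocks
#' at integer multiples `N` of the reference rate are synthesized by uniform
#' subdivision of each predicted reference period (phase-continuous), so a
#' change in scanner period is cancelled by a matching change in sampling
#' period.  With `zero_delay = TRUE` (the default) the steady-state mean
#' offset between the x1 output edges and the reference edges is zero.
#'
#' Gain mapping: the loop natural frequency is set so that the closed-loop
#' -3 dB point of the reference-to-output phase transfer equals
#' `loop_bandwidth` at the chosen damping, via the standard second-order
#' relation `w3dB = wn * sqrt(1 + 2 z^2 + sqrt((1 + 2 z^2)^2 + 1))`.
#'
#' @param loop_bandwidth closed-loop -3 dB bandwidth in Hz (e.g. 100 or 200).
#' @param damping dimensionless damping factor of the order-2 loop.
#' @param multipliers integer output multipliers N >= 1, e.g. `c(1, 1250)`
#'   for a denoised 8 kHz clock plus a phase-locked 10 MHz sampling clock, or
#'   `c(1, 6700)` for 12 kHz -> 80.4 MHz.
#' @param zero_delay logical; if `FALSE` the outputs are delayed by one
#'   nominal reference period (an uncompensated internal delay).
#' @return object of class `pll_config`.
#' @export
pll_config <- function(loop_bandwidth = 100, damping = 0.7,
                       multipliers = c(1L, 6700L), zero_delay = TRUE) {
  stopifnot(loop_bandwidth > 0, damping > 0,
            all(multipliers >= 1), all(multipliers == round(multipliers)))
  structure(list(loop_bandwidth = loop_bandwidth, damping = damping,
                 multipliers = as.integer(multipliers),
                 zero_delay = isTRUE(zero_delay)),
            class = "pll_config")
}

## -3dB scaling factor g(z): w3dB = wn * g(z) for the type-II closed loop.
pll_bw_factor <- function(damping) {
  a <- 1 + 2 * damping^2
  sqrt(a + sqrt(a^2 + 1))
}

## Proportional/integral gains of the edge-domain loop for reference period T:
## with phase predictor p[n+1] = p[n] + tau[n+1] + kp*e[n] and period
## integrator tau[n+1] = tau[n] + ki*e[n], the continuous-equivalent loop has
## 2*z*wn = (kp + ki)/T and wn^2 = ki/T^2.
pll_gains <- function(config, reference_rate) {
  T <- 1 / reference_rate
  wn <- 2 * pi * config$loop_bandwidth / pll_bw_factor(config$damping)
  if (wn * T >= 1) stop("pll_gains: loop bandwidth too high for the reference rate")
  ki <- (wn * T)^2
  kp <- 2 * config$damping * wn * T - ki
  if (kp <= 0) stop("pll_gains: gain mapping yields nonpositive proportional gain")
  list(kp = kp, ki = ki)
}

## Number of leading reference edges discarded as acquisition transient.
pll_settle_edges <- function(config, reference_rate) {
  max(1000L, ceiling(20 / config$loop_bandwidth * reference_rate))
}

#' Lock the PLL to a reference edge series
#'
#' Runs the discrete type-II loop over the reference edges: the phase error
#' at each edge is (reference edge time - predicted x1 edge time); the
#' period integrator and phase predictor are corrected with gains derived
#' from `(loop_bandwidth, damping)`.  The x1 output edges are the loop's
#' predicted edge times; each xN output subdivides a predicted x1 period
#' into N uniform intervals.  A settle interval of
#' `max(1000 edges, 20/loop_bandwidth seconds)` is discarded from the head
#' of every output, and the reference edges retained alongside it are
#' available in the result for paired statistics.
#'
#' @param reference an [edge_series()]; gaps exceeding 1.5 nominal periods
#'   are rejected (also enforced at construction).
#' @param config a [pll_config()].
#' @return list of class `pll_lock_result`: `clocks` (one `clock_series`
#'   per multiplier), `reference_retained` (edge_series aligned with the x1
#'   output), `settle_edges`, `gains`.
#' @export
pll_lock <- function(reference, config) {
  r <- reference$timestamps
  T0 <- reference$nominal_period
  n <- length(r)
  rate <- 1 / T0
  gaps <- which(diff(r) > 1.5 * T0)
  if (length(gaps)) {
    stop("pll_lock: reference gap exceeds 1.5 nominal periods at cycle ", gaps[1L])
  }
  settle <- pll_settle_edges(config, rate)
  if (n < settle + 10L) {
    stop("pll_lock: reference too short to converge: ", n, " edges, need > ",
         settle + 10L, " (settle interval + margin)")
  }
  g <- pll_gains(config, rate)
  p <- numeric(n)
  p[1L] <- r[1L]
  tau <- stats::median(diff(r[seq_len(min(n, 33L))]))
  kp <- g$kp; ki <- g$ki
  for (i in seq_len(n - 1L)) {
    e <- r[i] - p[i]
    tau <- tau + ki * e
    p[i + 1L] <- p[i] + tau + kp * e
  }
  if (!config$zero_delay) p <- p + T0
  keep <- (settle + 1L):n
  x1 <- p[keep]
  clocks <- lapply(config$multipliers, function(N) {
    ts <- if (N == 1L) x1 else {
      m <- length(x1)
      starts <- x1[-m]
      per <- diff(x1)
      as.vector(t(outer(starts, numeric(N), "+") +
                    outer(per, (0:(N - 1L)) / N)))
    }
    structure(list(timestamps = ts, nominal_period = T0 / N,
                   label = sprintf("pll_x%d", N), multiplier = N),
              class = c("clock_series", "edge_series"))
  })
  structure(list(clocks = clocks,
                 reference_retained = edge_series(r[keep], T0,
                                                  paste0(reference$label, "_retained")),
                 settle_edges = settle,
                 gains = g),
            class = "pll_lock_result")
}

#' Reference-to-output jitter transfer of the PLL
#'
#' Exact closed-form magnitude of the discrete loop's phase transfer
#' `H(z) = ((kp + ki)(z - 1) + ki) / ((z - 1)^2 + (kp + ki)(z - 1) + ki)`
#' evaluated at `z = exp(2i pi f / reference_rate)`.  The DC gain is exactly
#' 1 (drift tracking); jitter above the loop bandwidth is heavily attenuated.
#'
#' @param config a [pll_config()].
#' @param reference_rate reference edge rate in Hz.
#' @param frequencies jitter frequencies in Hz, in `(0, reference_rate / 2)`.
#' @return numeric vector of linear magnitude gains.
#' @export
jitter_transfer <- function(config, reference_rate, frequencies) {
  if (any(frequencies <= 0) || any(frequencies >= reference_rate / 2)) {
    stop("jitter_transfer: frequencies must lie strictly inside (0, reference_rate/2)")
  }
  g <- pll_gains(config, reference_rate)
  z <- exp(2i * pi * frequencies / reference_rate)
  a <- g$kp + g$ki
  num <- a * (z - 1) + g$ki
  den <- (z - 1)^2 + a * (z - 1) + g$ki
  Mod(num / den)
}

#' Effective number of averaged scanner periods
#'
#' The PLL's white-jitter variance reduction equals that of a rectangular
#' (boxcar) averager over `reference_rate / (2 * ENBW)` reference periods,
#' where ENBW is the equivalent-noise bandwidth of the jitter transfer,
#' `integral of |H(f)|^2 df` over `(0, reference_rate/2)`.  A 100 Hz loop on
#' a 12 kHz reference at damping 0.7 averages roughly 40 periods.
#'
#' @inheritParams jitter_transfer
#' @return dimensionless period count.
#' @export
effective_averaging_periods <- function(config, reference_rate) {
  enbw <- stats::integrate(function(f) jitter_transfer(config, reference_rate, f)^2,
                           lower = 1e-9, upper = reference_rate / 2 * (1 - 1e-12),
                           rel.tol = 1e-9, subdivisions = 2000L)$value
  reference_rate / (2 * enbw)
}
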