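#' Per-line slit-center jitter
#'
#' Localizes the slit center of each cycle's forward sweep with
#' [locate_peak_subsample()]; the mean-removed series of centers (in sample
#' units) is the imaging-jitter estimate.  Cycles whose fit fails (low SNR,
#' peak at boundary) are excluded and counted rather than aborting the run.
#'
#' @param record a `line_scan_record` acquired with a slit (or any
#'   single-peak) phantom.
#' @param upsample_factor passed to [locate_peak_subsample()].
#' @return [jitter_report()] in samples.
#' @export
slit_center_series <- function(record, upsample_factor = 16L) {
  S2 <- record$S %/% 2L
  centers <- apply(record$counts[, 1:S2, drop = FALSE], 1L, function(v) {
    tryCatch(locate_peak_subsample(v, upsample_factor),
             error = function(e) NA_real_)
  })
  jitter_report(centers[!is.na(centers)], units = "samples",
                label = "slit center (forward sweep)",
                n_excluded = sum(is.na(centers)))
}

#' Bidirectional misalignment via cross-correlation
#'
#' For each cycle the backward half-line is reversed, both halves are
#' up-sampled, mean-subtracted and cross-correlated, and the correlation
#' peak is refined by three-point parabolic interpolation.  Because a fixed
#' number of samples is assigned to each sweep, a line shift of dx samples
#' moves the forward image by +dx and the reversed backward image by -dx, so
#' the misalignment dd changes by 2 dx.  The reported per-cycle `delta_d` is
#' raw: it includes the record's constant bidirectional alignment offset
#' (for a slit at scan center on an even-S lattice, +1 sample, because
#' forward sample s mirrors onto backward sample S-1-s whose angle equals
#' that of forward sample s+1); jitter statistics are taken on the
#' mean-removed series, where the constant cancels.  Cycles whose
#' correlation peak sits at the search-window boundary, or with
#' |dd - median| >= S/4, are flagged.
#'
#' @param record a `line_scan_record` with structure in both sweeps.
#' @param upsample_factor integer up-sampling factor, default 16.
#' @param max_lag_samples half-width of the lag search window in original
#'   sample units (default S/8).
#' @return object of class `misalignment_series`: `delta_d` (samples),
#'   `delta_x = delta_d / 2`, `flagged` (logical per cycle), `n`.
#' @export
bidirectional_misalignment <- function(record, upsample_factor = 16L,
                                       max_lag_samples = NULL) {
  S <- record$S
  S2 <- S %/% 2L
  u <- as.integer(upsample_factor)
  if (is.null(max_lag_samples)) max_lag_samples <- S %/% 8L
  maxlag <- round(max_lag_samples * u)
  n_cycles <- nrow(record$counts)
  m <- S2 * u
  L <- 2^ceiling(log2(2L * m))
  lags_pos <- 0:(L %/% 2L - 1L)
  delta_d <- numeric(n_cycles)
  flagged <- logical(n_cycles)
  for (cyc in seq_len(n_cycles)) {
    fw <- upsample_fft(record$counts[cyc, 1:S2], u)
    bw <- upsample_fft(rev(record$counts[cyc, (S2 + 1L):S]), u)
    fw <- fw - mean(fw)
    bw <- bw - mean(bw)
    cc <- Re(stats::fft(stats::fft(c(fw, numeric(L - m))) *
                          Conj(stats::fft(c(bw, numeric(L - m)))),
                        inverse = TRUE)) / L
    ## cc[1 + k] = sum fw[i] * bw[i - k] for k >= 0; cc[L + 1 + k] for k < 0.
    ## reorder onto a contiguous lag axis -maxlag..maxlag
    lag_axis <- (-maxlag):maxlag
    seg <- cc[ifelse(lag_axis >= 0L, lag_axis + 1L, L + lag_axis + 1L)]
    ipk <- which.max(seg)
    at_boundary <- ipk == 1L || ipk == length(seg)
    im <- max(1L, ipk - 1L)
    ip <- min(length(seg), ipk + 1L)
    denom <- seg[im] - 2 * seg[ipk] + seg[ip]
    dd <- if (at_boundary || abs(denom) < .Machine$double.eps * max(abs(seg))) 0 else
      0.5 * (seg[im] - seg[ip]) / denom
    lag <- lag_axis[ipk] + dd
    ## a line shift of +dx moves the forward image +dx and the reversed
    ## backward image -dx, so the correlation peak sits at lag = +2 dx
    ## (plus the record's constant alignment offset)
    delta_d[cyc] <- lag / u
    flagged[cyc] <- at_boundary
  }
  flagged <- flagged | abs(delta_d - stats::median(delta_d)) >= S / 4
  structure(list(delta_d = delta_d, delta_x = delta_d / 2,
                 flagged = flagged, n = n_cycles, units = "samples"),
            class = "misalignment_series")
}

#' @export
print.misalignment_series <- function(x, ...) {
  ok <- !x$flagged
  cat(sprintf("<misalignment_series>: %d cycles (%d flagged), RMS dd = %.4g samples, RMS dx = %.4g samples\n",
              x$n, sum(x$flagged),
              sqrt(mean((x$delta_d[ok] - mean(x$delta_d[ok]))^2)),
              sqrt(mean((x$delta_x[ok] - mean(x$delta_x[ok]))^2))))
  invisible(x)
}

#' Averaged-periodogram (Welch) PSD of a jitter series
#'
#' Treats the per-event jitter series as uniformly sampled at `event_rate`
#' (per-cycle series at the line rate), splits it into Hann-windowed 50%
#' overlapping segments, and averages one-sided periodograms normalized so
#' that the integrated power equals the series variance (Parseval, with the
#' window power correction).
#'
#' @param report a [jitter_report()] (or plain numeric series).
#' @param event_rate events per second (Hz).
#' @param segment_length samples per segment; default
#'   `2^floor(log2(n/4))`, clamped to `[256, 4096]`.
#' @return object of class `psd_result`: `frequencies` (Hz), `power`
#'   (units^2/Hz), `segment_length`, `window`, `n_segments`.
#' @export
jitter_psd <- function(report, event_rate, segment_length = NULL) {
  x <- if (inherits(report, "jitter_report")) report$series else as.numeric(report)
  units <- if (inherits(report, "jitter_report")) report$units else "units"
  n <- length(x)
  if (n < 256L) stop("jitter_psd: need at least 256 events, got ", n)
  if (is.null(segment_length)) {
    segment_length <- 2^floor(log2(n / 4))
    segment_length <- min(max(segment_length, 256L), 4096L, 2^floor(log2(n)))
  }
  L <- as.integer(segment_length)
  if (L > n) stop("jitter_psd: segment_length exceeds series length")
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1L)) / L)
  U <- mean(w^2)
  step <- max(1L, L %/% 2L)
  starts <- seq(1L, n - L + 1L, by = step)
  acc <- numeric(L %/% 2L + 1L)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)
    P <- Mod(X[1:(L %/% 2L + 1L)])^2 / (L * U * event_rate)
    P[2:(L %/% 2L)] <- 2 * P[2:(L %/% 2L)]
    acc <- acc + P
  }
  structure(list(frequencies = (0:(L %/% 2L)) * event_rate / L,
                 power = acc / length(starts),
                 power_units = paste0(units, "^2/Hz"),
                 segment_length = L, window = "hann",
                 n_segments = length(starts)),
            class = "psd_result")
}

#' @export
print.psd_result <- function(x, ...) {
  cat(sprintf("<psd_result>: %d bins to %.4g Hz, %d x %d-sample Hann segments, integrated power %.6g\n",
              length(x$frequencies), max(x$frequencies), x$n_segments,
              x$segment_length, sum(x$power) * diff(x$frequencies[1:2])))
  invisible(x)
}

## separable boxcar smoothing (odd k), edges renormalized
box_smooth <- function(img, k = 5L) {
  kern <- rep(1, k)
  sm_dim <- function(m) {
    num <- apply(m, 2L, function(col) as.numeric(stats::filter(col, kern, sides = 2L)))
    den <- as.numeric(stats::filter(rep(1, nrow(m)), kern, sides = 2L))
    num / den
  }
  out <- sm_dim(img)
  out <- t(sm_dim(t(out)))
  out[is.na(out)] <- 0
  out
}

#' Track the centermost pulse across camera frames
#'
#' For every frame and sweep direction, locates the rendered pulse nearest
#' scan center with separable 2D subsample peak fitting (after median
#' background subtraction) and converts pixel coordinates to angles.  A
#' frame whose nearest-center pulse overlaps its neighbour too closely to
#' window (closer than `min_separation_px`) is flagged and excluded, the
#' same exclusion applied to overlapping edge pulses in the field.
#'
#' @param frames list of `camera_frame` objects from
#'   [acquire_camera_frames()].
#' @param upsample_factor passed to the 1D localizer.
#' @param min_separation_px minimum pulse separation in pixels.
#' @return data frame with columns `frame`, `sweep` (`"forward"` /
#'   `"backward"`), `fast_angle_rad`, `slow_angle_rad`; flagged frames are
#'   reported in `attr(, "flagged")`.
#' @export
track_2d_pulses <- function(frames, upsample_factor = 16L,
                            min_separation_px = 6) {
  stopifnot(length(frames) >= 2L)
  out <- list()
  flagged <- integer()
  for (fr in frames) {
    fast <- fr$fast_axis
    slow <- fr$slow_axis
    for (sweep in c("forward", "backward")) {
      img <- if (sweep == "forward") fr$image_forward else fr$image_backward
      bg <- stats::median(img)
      ## smooth before candidate detection so photon noise inside one spot
      ## does not split it into several pixel-scale maxima
      w <- box_smooth(img - bg, 5L)
      thr <- 0.3 * max(w)
      nr <- nrow(w); nc <- ncol(w)
      core <- w[2:(nr - 1L), 2:(nc - 1L)]
      ismax <- core >= thr &
        core >= w[1:(nr - 2L), 2:(nc - 1L)] & core >= w[3:nr, 2:(nc - 1L)] &
        core >= w[2:(nr - 1L), 1:(nc - 2L)] & core >= w[2:(nr - 1L), 3:nc]
      cand <- which(ismax, arr.ind = TRUE)
      if (nrow(cand) == 0L) { flagged <- c(flagged, fr$frame_index); next }
      cand_r <- cand[, 1L] + 1L
      cand_c <- cand[, 2L] + 1L
      ## cluster suppression: keep the strongest candidate within 5 px
      keep <- rep(TRUE, length(cand_r))
      strength <- w[cbind(cand_r, cand_c)]
      ord <- order(strength, decreasing = TRUE)
      for (ii in ord) {
        if (!keep[ii]) next
        close_by <- keep & (cand_r - cand_r[ii])^2 + (cand_c - cand_c[ii])^2 <= 25
        close_by[ii] <- FALSE
        keep[close_by] <- FALSE
      }
      cand_r <- cand_r[keep]
      cand_c <- cand_c[keep]
      cand <- cand[keep, , drop = FALSE]
      d2 <- fast[cand_c]^2 + slow[cand_r]^2
      i0 <- which.min(d2)
      sep <- if (nrow(cand) > 1L) {
        min(sqrt((cand_r[-i0] - cand_r[i0])^2 + (cand_c[-i0] - cand_c[i0])^2))
      } else Inf
      if (sep < min_separation_px) { flagged <- c(flagged, fr$frame_index); next }
      halfwin <- min(12L, max(3L, floor(sep / 2)))
      loc <- tryCatch(
        locate_peak_subsample_2d(img, upsample_factor,
                                 window_halfwidth = halfwin,
                                 center = c(cand_r[i0], cand_c[i0])),
        error = function(e) NULL)
      if (is.null(loc)) { flagged <- c(flagged, fr$frame_index); next }
      out[[length(out) + 1L]] <- data.frame(
        frame = fr$frame_index, sweep = sweep,
        fast_angle_rad = fast[1L] + loc[["col"]] * fr$pixel_pitch,
        slow_angle_rad = slow[1L] + loc[["row"]] * fr$pixel_pitch)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "flagged") <- unique(flagged)
  res
}

#' Intra-cycle jitter
#'
#' RMS of the mean-removed separation between the backward- and
#' forward-sweep center-pulse event times of each cycle.  Rigid per-cycle
#' (common-mode) shifts cancel; independent per-sweep noise adds in
#' quadrature; anticorrelated (mirrored) sweep jitter partially cancels.
#'
#' @param forward,backward per-cycle event times (seconds), paired by index.
#' @return [jitter_report()] in seconds.
#' @export
intra_cycle_jitter <- function(forward, backward) {
  if (length(forward) != length(backward)) {
    stop("intra_cycle_jitter: forward/backward pairing mismatch (",
         length(forward), " vs ", length(backward), ")")
  }
  jitter_report(backward - forward, units = "s", label = "intra-cycle")
}

#' Percent reduction between two RMS jitter figures
#'
#' `100 * (before - after) / before`; summaries round to the nearest
#' integer percent (see [percent_reduction_label()]).
#'
#' @param before_rms,after_rms nonnegative RMS values; `before_rms` must be
#'   positive.
#' @return percent as a plain number.
#' @export
percent_reduction <- function(before_rms, after_rms) {
  if (!is.finite(before_rms) || before_rms <= 0) {
    stop("percent_reduction: before_rms must be positive")
  }
  100 * (before_rms - after_rms) / before_rms
}

#' @rdname percent_reduction
#' @export
percent_reduction_label <- function(before_rms, after_rms) {
  sprintf("%d%%", round(percent_reduction(before_rms, after_rms)))
}
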