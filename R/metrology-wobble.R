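#' Direct least-squares ellipse fit to a 2D scan path
#'
#' Fits a conic constrained to be an ellipse (Halir-Flusser numerically
#' stable formulation of the Fitzgibbon direct least-squares fit) to
#' (fast, slow) trajectory points, after centering and per-axis scaling so
#' that the extreme aspect ratios of scanner wobble paths (semi-major on
#' the order of the scan amplitude, semi-minor of a few hundred microradians
#' or less) stay well conditioned.  Degenerate (collinear / flat) point sets
#' return a flagged fit with semi-minor axis 0.
#'
#' @param fast,slow numeric vectors of fast- and slow-axis angles
#'   (radians); alternatively `fast` may be a 2-column matrix or data frame.
#' @return object of class `wobble_fit`: `center` (length-2), `semi_major`,
#'   `semi_minor` (radians), `tilt` (radians, major-axis direction),
#'   `rms_residual` (radians, Sampson distance), `degenerate`.
#' @export
fit_wobble_ellipse <- function(fast, slow = NULL) {
  if (is.null(slow)) {
    m <- as.matrix(fast)
    stopifnot(ncol(m) == 2L)
    fast <- m[, 1L]; slow <- m[, 2L]
  }
  stopifnot(length(fast) == length(slow), length(fast) >= 6L)
  mx <- mean(fast); my <- mean(slow)
  sx <- stats::sd(fast); sy <- stats::sd(slow)
  if (sx <= 0) stop("fit_wobble_ellipse: fast-axis coordinates are constant")
  if (sy <= .Machine$double.eps * max(sx, 1)) {
    return(degenerate_wobble_fit(fast, slow))
  }
  u <- (fast - mx) / sx
  v <- (slow - my) / sy
  D1 <- cbind(u^2, u * v, v^2)
  D2 <- cbind(u, v, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(Tm)) return(degenerate_wobble_fit(fast, slow))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3L, ] / 2, -M[2L, ], M[1L, ] / 2)  # inv(C1) %*% M
  ev <- eigen(M)
  cond <- Re(4 * ev$vectors[1L, ] * ev$vectors[3L, ] - ev$vectors[2L, ]^2)
  ok <- which(cond > 0 & abs(Im(ev$values)) < 1e-8)
  if (!length(ok)) return(degenerate_wobble_fit(fast, slow))
  a1 <- Re(ev$vectors[, ok[1L]])
  coef_n <- c(a1, as.vector(Tm %*% a1))  # (a, b, c, d, e, g) in scaled coords
  a <- coef_n[1L]; b <- coef_n[2L]; cc <- coef_n[3L]
  d <- coef_n[4L]; e <- coef_n[5L]; g <- coef_n[6L]
  ## back-transform to original coordinates: u = (x - mx)/sx, v = (y - my)/sy
  A <- a / sx^2
  B <- b / (sx * sy)
  C <- cc / sy^2
  D <- -2 * a * mx / sx^2 - b * my / (sx * sy) + d / sx
  E <- -2 * cc * my / sy^2 - b * mx / (sx * sy) + e / sy
  Fc0 <- a * mx^2 / sx^2 + b * mx * my / (sx * sy) + cc * my^2 / sy^2 -
    d * mx / sx - e * my / sy + g
  M33 <- matrix(c(A, B / 2, B / 2, C), 2L)
  center <- tryCatch(solve(M33, -c(D, E) / 2), error = function(e) NULL)
  if (is.null(center)) return(degenerate_wobble_fit(fast, slow))
  Fc <- A * center[1L]^2 + B * prod(center) + C * center[2L]^2 +
    D * center[1L] + E * center[2L] + Fc0
  eg <- eigen(M33, symmetric = TRUE)
  ax2 <- -Fc / eg$values
  if (any(ax2 <= 0)) return(degenerate_wobble_fit(fast, slow))
  axes <- sqrt(ax2)
  imaj <- which.max(axes)
  tilt <- atan2(eg$vectors[2L, imaj], eg$vectors[1L, imaj])
  if (tilt > pi / 2) tilt <- tilt - pi
  if (tilt <= -pi / 2) tilt <- tilt + pi
  ## Sampson (gradient-normalized algebraic) residual
  Q <- A * fast^2 + B * fast * slow + C * slow^2 + D * fast + E * slow + Fc0
  gx <- 2 * A * fast + B * slow + D
  gy <- 2 * C * slow + B * fast + E
  res <- Q / pmax(sqrt(gx^2 + gy^2), .Machine$double.xmin)
  structure(list(center = as.numeric(center),
                 semi_major = max(axes), semi_minor = min(axes),
                 tilt = tilt, rms_residual = sqrt(mean(res^2)),
                 degenerate = FALSE),
            class = "wobble_fit")
}

degenerate_wobble_fit <- function(fast, slow) {
  ## flat path: report the line's extent as semi-major, zero semi-minor
  cf <- stats::coef(stats::lm(slow ~ fast))
  tilt <- atan(cf[[2L]])
  res <- slow - (cf[[1L]] + cf[[2L]] * fast)
  structure(list(center = c(mean(fast), mean(slow)),
                 semi_major = diff(range(fast)) / 2 / cos(tilt),
                 semi_minor = 0, tilt = tilt,
                 rms_residual = sqrt(mean(res^2)),
                 degenerate = TRUE),
            class = "wobble_fit")
}

#' @export
print.wobble_fit <- function(x, ...) {
  cat(sprintf("<wobble_fit%s>: center (%.4g, %.4g) rad, semi-major %.4g rad, semi-minor %.4g rad, tilt %.4g rad, rms residual %.3g rad\n",
              if (x$degenerate) " (degenerate)" else "",
              x$center[1L], x$center[2L], x$semi_major, x$semi_minor,
              x$tilt, x$rms_residual))
  invisible(x)
}

#' FWHM broadening under frame averaging
#'
#' Averages blocks of `n` consecutive scan lines for each requested count,
#' measures the slit FWHM of every averaged forward-sweep line, and reports
#' the widening relative to both the jitter-free ideal width (the record's
#' noiseless template) and the measured single-line width.  Line jitter
#' broadens the averaged profile by convolution with the jitter
#' distribution, so for Gaussian jitter of sigma_j samples the asymptotic
#' width is `sqrt(w0^2 + 8 ln 2 sigma_j^2)`.
#'
#' @param record a `line_scan_record` with a slit phantom.
#' @param frame_counts integer vector of averaging depths (e.g.
#'   `c(1, 2, 4, 8)`); the record must hold at least `max(frame_counts)`
#'   cycles.
#' @return object of class `fwhm_curve`: `frame_counts`, `fwhm_mean`,
#'   `fwhm_sd`, `n_blocks`, `widening_vs_ideal`, `widening_vs_single`,
#'   `reference_ideal`, `reference_single` (all widths in samples).
#' @export
averaging_broadening_curve <- function(record, frame_counts = c(1L, 2L, 4L, 8L)) {
  frame_counts <- sort(unique(as.integer(frame_counts)))
  stopifnot(all(frame_counts >= 1L))
  n_lines <- nrow(record$counts)
  if (n_lines < max(frame_counts)) {
    stop("averaging_broadening_curve: record has ", n_lines,
         " cycles but ", max(frame_counts), "-frame averaging was requested")
  }
  S2 <- record$S %/% 2L
  fwd <- record$counts[, 1:S2, drop = FALSE]
  measure <- function(n_avg) {
    n_blocks <- n_lines %/% n_avg
    vals <- vapply(seq_len(n_blocks), function(b) {
      rows <- ((b - 1L) * n_avg + 1L):(b * n_avg)
      prof <- colMeans(fwd[rows, , drop = FALSE])
      tryCatch(fwhm(prof), error = function(e) NA_real_)
    }, numeric(1L))
    vals[!is.na(vals)]
  }
  res <- lapply(frame_counts, measure)
  fm <- vapply(res, mean, numeric(1L))
  fs <- vapply(res, stats::sd, numeric(1L))
  ref_ideal <- fwhm(record$template[1:S2])
  ref_single <- if (1L %in% frame_counts) fm[frame_counts == 1L] else
    mean(measure(1L))
  structure(list(frame_counts = frame_counts,
                 fwhm_mean = fm, fwhm_sd = fs,
                 n_blocks = vapply(res, length, integer(1L)),
                 widening_vs_ideal = fm - ref_ideal,
                 widening_vs_single = fm - ref_single,
                 reference_ideal = ref_ideal,
                 reference_single = ref_single,
                 units = "samples"),
            class = "fwhm_curve")
}

#' @export
print.fwhm_curve <- function(x, ...) {
  cat("<fwhm_curve> (samples):\n")
  print(data.frame(frames = x$frame_counts, fwhm = x$fwhm_mean,
                   widening_vs_ideal = x$widening_vs_ideal,
                   widening_vs_single = x$widening_vs_single))
  cat(sprintf("reference: ideal %.4g, single-frame %.4g\n",
              x$reference_ideal, x$reference_single))
  invisible(x)
}
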