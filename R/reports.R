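#' Jitter report
#'
#' The package-wide definition of jitter: the mean-removed per-event series
#' (mean removal, not detrending — slow drift is analyzed in the PSD domain
#' instead), its RMS, its maximum absolute value and the event count, with a
#' units tag carried along so downstream unit conversions stay honest.
#'
#' @param series numeric per-event values (seconds, samples or radians); the
#'   mean is removed here.
#' @param units units tag, e.g. `"s"`, `"samples"`, `"rad"`.
#' @param label optional free-text provenance.
#' @param n_excluded events dropped upstream (failed fits), recorded for
#'   bookkeeping.
#' @return object of class `jitter_report` with fields `series` (mean
#'   removed), `rms`, `max_abs`, `n`, `mean_removed` (the removed mean),
#'   `units`, `label`, `n_excluded`.
#' @export
jitter_report <- function(series, units = "s", label = "", n_excluded = 0L) {
  series <- as.numeric(series)
  series <- series[is.finite(series)]
  mu <- mean(series)
  centered <- series - mu
  structure(list(series = centered,
                 rms = sqrt(mean(centered^2)),
                 max_abs = max(abs(centered)),
                 n = length(centered),
                 mean_removed = mu,
                 units = units, label = label,
                 n_excluded = as.integer(n_excluded)),
            class = "jitter_report")
}

#' @export
print.jitter_report <- function(x, ...) {
  cat(sprintf("<jitter_report%s>: n = %d, RMS = %.6g %s, max |.| = %.6g %s%s\n",
              if (nzchar(x$label)) paste0(" ", x$label) else "",
              x$n, x$rms, x$units, x$max_abs, x$units,
              if (x$n_excluded > 0) sprintf(" (%d events excluded)", x$n_excluded) else ""))
  invisible(x)
}

## Serializable form (units embedded); `series` included on request only.
report_payload <- function(x, include_series = FALSE) {
  out <- list(n = x$n, rms = x$rms, max_abs = x$max_abs,
              mean_removed = x$mean_removed, units = x$units,
              label = x$label, n_excluded = x$n_excluded)
  if (include_series) out$series <- x$series
  out
}

#' Write a report object as JSON
#'
#' Serializes `jitter_report`, `psd_result`, `wobble_fit` and `fwhm_curve`
#' objects (units embedded in the payload) with `jsonlite`.
#'
#' @param x object to serialize.
#' @param path file path.
#' @param include_series logical; include full per-event series.
#' @export
write_report_json <- function(x, path, include_series = FALSE) {
  payload <- if (inherits(x, "jitter_report")) {
    report_payload(x, include_series)
  } else if (inherits(x, "psd_result")) {
    list(frequencies_hz = x$frequencies, power = x$power,
         power_units = x$power_units, segment_length = x$segment_length,
         window = x$window, n_segments = x$n_segments)
  } else {
    unclass(x)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
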