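#' Timestamped edge series
#'
#' Container for the rising-edge times of a logic-level signal: the scanner
#' position-feedback TTL, the true mirror turnarounds, or a synthesized PLL
#' clock.  Edges must be strictly increasing and every successive spacing
#' must lie within +/-20% of the nominal period; anything else is rejected as
#' malformed rather than silently accepted, because downstream pairing of
#' edges by cycle index presumes no missing or doubled edges.
#'
#' @param timestamps numeric vector of edge times in seconds, strictly
#'   increasing.
#' @param nominal_period nominal edge spacing in seconds.
#' @param label free-text label, e.g. `"feedback"`, `"optical"`, `"pll_x1"`.
#' @return an object of class `edge_series` with fields `timestamps`,
#'   `nominal_period`, `label`.
#' @export
edge_series <- function(timestamps, nominal_period, label = "edges") {
  timestamps <- as.numeric(timestamps)
  stopifnot(is.numeric(nominal_period), nominal_period > 0,
            length(timestamps) >= 2L)
  d <- diff(timestamps)
  if (any(d <= 0)) {
    stop("edge_series '", label, "': timestamps must be strictly increasing (first violation at edge ",
         which(d <= 0)[1L] + 1L, ")")
  }
  bad <- which(abs(d - nominal_period) > 0.2 * nominal_period)
  if (length(bad)) {
    stop("edge_series '", label, "': edge spacing deviates more than 20% from the nominal period at edge ",
         bad[1L] + 1L, " (spacing ", signif(d[bad[1L]], 6), " s vs nominal ",
         signif(nominal_period, 6), " s)")
  }
  structure(list(timestamps = timestamps, nominal_period = nominal_period,
                 label = label),
            class = "edge_series")
}

#' @export
print.edge_series <- function(x, ...) {
  cat(sprintf("<edge_series '%s'>: %d edges, nominal period %.6g s (%.6g Hz)\n",
              x$label, length(x$timestamps), x$nominal_period,
              1 / x$nominal_period))
  invisible(x)
}

#' @export
length.edge_series <- function(x) length(x$timestamps)

#' Write / read an edge series as CSV
#'
#' Two columns `index,timestamp_s` with a header line; `index` is 0-based.
#' Clock series (see [pll_lock()]) carry an extra leading comment line
#' `# multiplier=<N>`.
#'
#' @param x an `edge_series` or `clock_series`.
#' @param path file path.
#' @return `write_edge_series_csv` returns `path` invisibly;
#'   `read_edge_series_csv` returns an `edge_series` (or `clock_series` if a
#'   multiplier comment is present).
#' @export
write_edge_series_csv <- function(x, path) {
  con <- file(path, open = "wb")  # binary: force LF line endings
  on.exit(close(con))
  hdr <- character()
  if (inherits(x, "clock_series")) {
    hdr <- c(hdr, sprintf("# multiplier=%d", x$multiplier))
  }
  hdr <- c(hdr, sprintf("# nominal_period_s=%.17g", x$nominal_period),
           sprintf("# label=%s", x$label))
  writeLines(c(hdr, "index,timestamp_s",
               sprintf("%d,%.17g", seq_along(x$timestamps) - 1L, x$timestamps)),
             con, sep = "\n")
  invisible(path)
}

#' @rdname write_edge_series_csv
#' @export
read_edge_series_csv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  get_meta <- function(key) {
    m <- grep(paste0("^# ", key, "="), meta, value = TRUE)
    if (length(m)) sub(paste0("^# ", key, "="), "", m[1L]) else NULL
  }
  per <- as.numeric(get_meta("nominal_period_s"))
  lab <- get_meta("label")
  if (is.null(lab)) lab <- "edges"
  if (!length(per) || is.na(per)) per <- stats::median(diff(df$timestamp_s))
  es <- edge_series(df$timestamp_s, per, lab)
  mult <- get_meta("multiplier")
  if (!is.null(mult)) {
    es$multiplier <- as.integer(mult)
    class(es) <- c("clock_series", class(es))
  }
  es
}
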