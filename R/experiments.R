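#' Exact unit conversions for jitter figures
#'
#' Converts jitter magnitudes between sampling-clock samples, seconds and
#' mirror angle (radians) using the scan-center slope of the sinusoidal
#' trajectory: an angle deviation `theta` near scan center corresponds to a
#' time deviation `t = theta / (Theta * 2 * pi * f)`, and a time deviation
#' to `t * sample_rate` samples.  With a `diffraction_angle` in the context,
#' `to = "diffraction"` reports the angle divided by the diffraction-limited
#' angular resolution.
#'
#' @param value numeric value(s) to convert.
#' @param from,to one of `"samples"`, `"seconds"`, `"radians"` (and
#'   `"diffraction"` for `to`).
#' @param context named list supplying what the conversion needs:
#'   `sample_rate` (Hz) for samples, `amplitude` (rad) and `line_rate` (Hz)
#'   for radians, `diffraction_angle` (rad) for the diffraction ratio.
#' @return converted value(s).
#' @export
convert_units <- function(value, from = c("samples", "seconds", "radians"),
                          to = c("samples", "seconds", "radians", "diffraction"),
                          context = list()) {
  from <- match.arg(from)
  to <- match.arg(to)
  need <- function(field) {
    if (is.null(context[[field]])) {
      stop("convert_units: context is missing required field '", field, "'")
    }
    context[[field]]
  }
  center_slope <- function() need("amplitude") * 2 * pi * need("line_rate")
  seconds <- switch(from,
                    samples = value / need("sample_rate"),
                    seconds = value,
                    radians = value / center_slope())
  switch(to,
         samples = seconds * need("sample_rate"),
         seconds = seconds,
         radians = seconds * center_slope(),
         diffraction = seconds * center_slope() / need("diffraction_angle"))
}

#' Experiment configuration
#'
#' Bundles everything one of the canned experiment drivers needs: the
#' scanner, the PLL, the trigger/clock matrix, the phantom and the run
#' seed.  `experiment_config(id, seed)` fills documented desk-scale
#' defaults for the chosen id (simulations are scaled down from the
#' hardware scale -- fewer samples per line, fewer cycles -- so a driver
#' finishes in seconds; every default can be overridden via `...`).  The
#' seed is mandatory: no silent nondeterminism.
#'
#' @param id one of `"fig3"`, `"fig4"`, `"fig5"`, `"fig6"`, `"fig7"`,
#'   `"fig8"`.
#' @param seed integer run seed (required).
#' @param ... named overrides of the id's default parameters.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(id = c("fig3", "fig4", "fig5", "fig6", "fig7", "fig8"),
                              seed, ...) {
  id <- match.arg(id)
  if (missing(seed)) stop("experiment_config: seed is mandatory")
  defaults <- switch(id,
    fig3 = list(nominal_frequency = 8000, amplitude = 10 * pi / 180,
                feedback_white_rms = 3.38e-9, mirror_jitter_rms = 0.5e-9,
                band_components = list(c(30, 1.0e-9), c(60, 0.8e-9), c(150, 0.6e-9)),
                loop_bandwidth = 200, damping = 0.7, n_edges = 6000L),
    fig4 = list(nominal_frequency = 8000, amplitude = 10 * pi / 180,
                ellipse_semi_minor = 400e-6, pulse_period = 100e-9,
                trajectory_cycles = 2L),
    fig5 = list(nominal_frequency = 12000, amplitude = 5 * pi / 180,
                slow_axis_jitter_rms = 13.49e-6, mirror_jitter_rms = 0.8e-9,
                hf_oscillation_amplitude = 5e-6, n_frames = 60L,
                frame_rate = 8, pulse_period = 100e-9),
    fig6 = list(nominal_frequency = 12000, amplitude = 5 * pi / 180,
                samples_per_cycle = 200L, n_cycles = 400L,
                feedback_jitter_samples = 0.27, mirror_jitter_rms = 0.5e-9,
                loop_bandwidth = 100, damping = 0.7,
                slit_width_samples = 8, slit_psf_samples = 3,
                photon_scale = 2000, background = 10),
    fig7 = list(nominal_frequency = 8000, amplitude = 10 * pi / 180,
                samples_per_cycle = 200L, n_cycles = 2048L,
                feedback_jitter_samples = 0.3, mirror_jitter_rms = 0.5e-9,
                loop_bandwidth = 100, damping = 0.7, free_run_offset = 10,
                emitter_density = NULL,  # filled per amplitude below
                photon_scale = 1500, background = 10),
    fig8 = list(nominal_frequency = 12000, amplitude = 5 * pi / 180,
                samples_per_cycle = 200L, n_cycles = 512L,
                feedback_jitter_samples = 0.27, mirror_jitter_rms = 0.5e-9,
                loop_bandwidth = 100, damping = 0.7,
                slit_width_samples = 8, slit_psf_samples = 3,
                photon_scale = 2000, background = 10,
                frame_counts = c(1L, 2L, 4L, 8L, 16L)))
  params <- utils::modifyList(defaults, list(...))
  structure(list(id = id, seed = as.integer(seed), params = params),
            class = "experiment_config")
}

## stable non-cryptographic hash (djb2) of the serialized config
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  h <- 5381
  for (ch in utf8ToInt(as.character(s))) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

## the four line-trigger x sampling-clock combinations
four_configurations <- function() {
  list(fb_async  = c(trigger = "position_feedback", clock = "free_running"),
       fb_pll    = c(trigger = "position_feedback", clock = "pll_locked"),
       pll_async = c(trigger = "pll_x1", clock = "free_running"),
       pll_pll   = c(trigger = "pll_x1", clock = "pll_locked"))
}

## slit phantom sized in sample units of a given acquisition geometry
slit_for <- function(amplitude, S, width_samples, psf_samples,
                     photon_scale, background) {
  rad_per_sample <- amplitude * 2 * pi / S  # center slope, per sample
  phantom_slit(center = 0, width = width_samples * rad_per_sample,
               psf_sigma = psf_samples * rad_per_sample,
               photon_scale = photon_scale, background = background)
}

write_csv_lf <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  fmt <- function(v) if (is.numeric(v)) sprintf("%.12g", v) else as.character(v)
  body <- do.call(paste, c(lapply(df, fmt), sep = ","))
  writeLines(c(paste(names(df), collapse = ","), body), con, sep = "\n")
  invisible(path)
}

#' Run a canned experiment end to end
#'
#' Simulates, measures and writes a result bundle under `out_dir`: a
#' `manifest.json` (config, seed, config hash), a `summary.csv` shaped like
#' the corresponding results table, and per-configuration subdirectories
#' with jitter reports (JSON), series (CSV) and -- for imaging drivers --
#' line-scan TIFF stacks.  Identical config and seed give byte-identical
#' outputs.
#'
#' @param config an [experiment_config()].
#' @param out_dir output directory (created if needed).
#' @param write_images logical; write TIFF stacks of the acquired records.
#' @return the result list, invisibly (also serialized to disk).
#' @export
run_experiment <- function(config, out_dir, write_images = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- switch(config$id,
                fig3 = experiment_fig3(config, out_dir),
                fig4 = experiment_fig4(config, out_dir),
                fig5 = experiment_fig5(config, out_dir),
                fig6 = experiment_fig6(config, out_dir, write_images),
                fig7 = experiment_fig7(config, out_dir, write_images),
                fig8 = experiment_fig8(config, out_dir))
  manifest <- list(id = config$id, seed = config$seed,
                   config = unclass(config), hash = config_hash(config))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

## -- drivers ----------------------------------------------------------------

experiment_fig3 <- function(config, out_dir) {
  p <- config$params
  spec <- scanner_spec(nominal_frequency = p$nominal_frequency,
                       amplitude = p$amplitude,
                       mirror_jitter_rms = p$mirror_jitter_rms,
                       drift = drift_model("random_walk"),
                       feedback_noise = feedback_noise_spec(
                         white_rms = p$feedback_white_rms,
                         band_components = p$band_components))
  pll <- pll_config(p$loop_bandwidth, p$damping, multipliers = 1L)
  n_need <- pll_settle_edges(pll, p$nominal_frequency) + p$n_edges
  edges <- generate_feedback_edges(spec, (n_need + 2) / p$nominal_frequency,
                                   seed = config$seed)
  lock <- pll_lock(edges$feedback, pll)
  keep <- (lock$settle_edges + 1L):length(edges$feedback$timestamps)
  fb_kept <- edge_series(edges$feedback$timestamps[keep], edges$feedback$nominal_period, "feedback")
  tr_kept <- edge_series(edges$true_turnarounds$timestamps[keep],
                         edges$true_turnarounds$nominal_period, "optical")
  rep_fb_opt <- relative_edge_jitter(fb_kept, tr_kept)
  rep_pll_opt <- relative_edge_jitter(lock$clocks[[1L]], tr_kept)
  rep_fb_pll <- relative_edge_jitter(fb_kept, lock$clocks[[1L]])
  psd_fb <- jitter_psd(rep_fb_opt, p$nominal_frequency)
  psd_pll <- jitter_psd(rep_pll_opt, p$nominal_frequency)
  summary <- data.frame(signal_1 = c("Position feedback", "Position feedback", "PLL"),
                        signal_2 = c("PLL", "Optical", "Optical"),
                        jitter_ns = c(rep_fb_pll$rms, rep_fb_opt$rms,
                                      rep_pll_opt$rms) * 1e9)
  write_csv_lf(summary, file.path(out_dir, "summary.csv"))
  write_report_json(rep_fb_opt, file.path(out_dir, "jitter_feedback_vs_optical.json"))
  write_report_json(rep_pll_opt, file.path(out_dir, "jitter_pll_vs_optical.json"))
  write_report_json(psd_fb, file.path(out_dir, "psd_feedback.json"))
  write_report_json(psd_pll, file.path(out_dir, "psd_pll.json"))
  list(summary = summary, reports = list(fb_opt = rep_fb_opt, pll_opt = rep_pll_opt,
                                         fb_pll = rep_fb_pll),
       psd = list(feedback = psd_fb, pll = psd_pll))
}

experiment_fig4 <- function(config, out_dir) {
  p <- config$params
  spec <- scanner_spec(nominal_frequency = p$nominal_frequency,
                       amplitude = p$amplitude,
                       wobble = wobble_spec(ellipse_semi_minor = p$ellipse_semi_minor))
  times <- seq(0, p$trajectory_cycles / p$nominal_frequency, by = p$pulse_period)
  traj <- simulate_trajectory(spec, times, seed = config$seed)
  fit <- fit_wobble_ellipse(traj$fast_angle_rad, traj$slow_angle_rad)
  write_trajectory_csv(traj, file.path(out_dir, "trajectory.csv"))
  write_report_json(fit, file.path(out_dir, "wobble_fit.json"))
  summary <- data.frame(semi_major_rad = fit$semi_major,
                        semi_minor_rad = fit$semi_minor,
                        rms_residual_rad = fit$rms_residual)
  write_csv_lf(summary, file.path(out_dir, "summary.csv"))
  list(fit = fit, trajectory = traj, summary = summary)
}

experiment_fig5 <- function(config, out_dir) {
  p <- config$params
  spec <- scanner_spec(nominal_frequency = p$nominal_frequency,
                       amplitude = p$amplitude,
                       mirror_jitter_rms = p$mirror_jitter_rms,
                       wobble = wobble_spec(
                         hf_oscillation_amplitude = p$hf_oscillation_amplitude,
                         slow_axis_jitter_rms = p$slow_axis_jitter_rms))
  frames <- acquire_camera_frames(spec, pulse_period = p$pulse_period,
                                  n_frames = p$n_frames,
                                  frame_rate = p$frame_rate,
                                  seed = config$seed)
  tracked <- track_2d_pulses(frames)
  slope <- p$amplitude * 2 * pi * p$nominal_frequency
  rows <- list()
  for (sweep in c("forward", "backward")) {
    sub <- tracked[tracked$sweep == sweep, ]
    fast_rep <- jitter_report(sub$fast_angle_rad, units = "rad",
                              label = paste("fast-axis", sweep))
    slow_rep <- jitter_report(sub$slow_angle_rad, units = "rad",
                              label = paste("slow-axis", sweep))
    rows[[paste0("fast_", sweep)]] <-
      data.frame(source = paste0("Fast-axis ", sweep),
                 angle_urad = fast_rep$rms * 1e6,
                 time_ns = fast_rep$rms / slope * 1e9)
    rows[[paste0("slow_", sweep)]] <-
      data.frame(source = paste0("Slow-axis ", sweep),
                 angle_urad = slow_rep$rms * 1e6,
                 time_ns = slow_rep$rms / slope * 1e9)
  }
  fwd <- tracked[tracked$sweep == "forward", ]
  bwd <- tracked[tracked$sweep == "backward", ]
  common <- intersect(fwd$frame, bwd$frame)
  icj <- intra_cycle_jitter(fwd$fast_angle_rad[match(common, fwd$frame)] / slope,
                            -bwd$fast_angle_rad[match(common, bwd$frame)] / slope)
  rows$intra <- data.frame(source = "Fast-axis intra-cycle",
                           angle_urad = icj$rms * slope * 1e6,
                           time_ns = icj$rms * 1e9)
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  write_csv_lf(summary, file.path(out_dir, "summary.csv"))
  write_csv_lf(tracked, file.path(out_dir, "tracked_pulses.csv"))
  list(summary = summary, tracked = tracked, intra_cycle = icj)
}

line_scan_matrix_run <- function(p, seed, phantom_builder, write_images, out_dir) {
  f <- p$nominal_frequency
  S <- p$samples_per_cycle
  rate <- S * f
  spec <- scanner_spec(nominal_frequency = f, amplitude = p$amplitude,
                       mirror_jitter_rms = p$mirror_jitter_rms,
                       drift = drift_model("random_walk"),
                       feedback_noise = feedback_noise_spec(
                         white_rms = p$feedback_jitter_samples / rate))
  pll <- pll_config(p$loop_bandwidth, p$damping, multipliers = 1L)
  trig <- function(src) trigger_config(src, S)
  clk <- function(mode) clock_spec(mode, nominal_rate = rate,
                                   free_run_offset = if (is.null(p$free_run_offset)) 7.3 else p$free_run_offset)
  records <- list()
  for (nm in names(four_configurations())) {
    cfg <- four_configurations()[[nm]]
    rec <- acquire_line_scan(spec, trig(cfg[["trigger"]]), clk(cfg[["clock"]]),
                             phantom_builder(), n_cycles = p$n_cycles,
                             seed = seed, pll = pll)
    records[[nm]] <- rec
    sub <- file.path(out_dir, nm)
    dir.create(sub, showWarnings = FALSE)
    if (write_images) {
      write_tiff16(lapply(seq_len(nrow(rec$counts)),
                          function(i) matrix(rec$counts[i, ], nrow = 1L)),
                   file.path(sub, "line_scan.tif"))
    }
    write_csv_lf(data.frame(cycle = seq_len(p$n_cycles) - 1L,
                            trigger_time_s = rec$trigger_times,
                            quant_error_samples = rec$quant_error_samples),
                 file.path(sub, "ground_truth.csv"))
  }
  list(spec = spec, records = records, rate = rate)
}

experiment_fig6 <- function(config, out_dir, write_images = FALSE) {
  p <- config$params
  run <- line_scan_matrix_run(p, config$seed,
                              function() slit_for(p$amplitude, p$samples_per_cycle,
                                                  p$slit_width_samples, p$slit_psf_samples,
                                                  p$photon_scale, p$background),
                              write_images, out_dir)
  rows <- list()
  for (nm in names(run$records)) {
    rec <- run$records[[nm]]
    sc <- slit_center_series(rec)
    bd <- bidirectional_misalignment(rec)
    dx <- jitter_report(bd$delta_x[!bd$flagged], units = "samples",
                        label = paste0(nm, " bidirectional dx"))
    write_report_json(sc, file.path(out_dir, nm, "slit_center.json"))
    write_report_json(dx, file.path(out_dir, nm, "bidirectional_dx.json"))
    write_csv_lf(data.frame(cycle = seq_len(bd$n) - 1L, delta_d = bd$delta_d,
                            flagged = as.integer(bd$flagged)),
                 file.path(out_dir, nm, "misalignment.csv"))
    cfg <- four_configurations()[[nm]]
    rows[[nm]] <- data.frame(
      line_trigger = if (cfg[["trigger"]] == "pll_x1") "PLL" else "Pos. feedback",
      sampling_clock = if (cfg[["clock"]] == "pll_locked") "PLL" else "Asynchronous",
      samples_rms = dx$rms,
      time_ns = dx$rms / run$rate * 1e9,
      slit_center_rms_samples = sc$rms)
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  summary$percent_reduction_vs_unsuppressed <-
    round(percent_reduction(summary$samples_rms[1L], summary$samples_rms))
  write_csv_lf(summary, file.path(out_dir, "summary.csv"))
  list(summary = summary, records = run$records)
}

experiment_fig7 <- function(config, out_dir, write_images = FALSE) {
  p <- config$params
  if (is.null(p$emitter_density)) {
    ## a few tens of resolvable emitters across the scan range
    p$emitter_density <- 40 / (2 * p$amplitude * 4 * (3 * p$amplitude * 2 * pi / p$samples_per_cycle))
  }
  run <- line_scan_matrix_run(p, config$seed, function() {
    rad_per_sample <- p$amplitude * 2 * pi / p$samples_per_cycle
    phantom_powder(emitter_density = p$emitter_density,
                   emitter_sigma = 1.5 * rad_per_sample,
                   psf_sigma = 2 * rad_per_sample,
                   photon_scale = p$photon_scale, background = p$background)
  }, write_images, out_dir)
  rows <- list()
  psd_async <- NULL
  for (nm in names(run$records)) {
    rec <- run$records[[nm]]
    bd <- bidirectional_misalignment(rec)
    dx <- jitter_report(bd$delta_x[!bd$flagged], units = "samples",
                        label = paste0(nm, " bidirectional dx"))
    write_report_json(dx, file.path(out_dir, nm, "bidirectional_dx.json"))
    if (nm == "pll_async") {
      psd_async <- jitter_psd(jitter_report(bd$delta_x, units = "samples"),
                              p$nominal_frequency)
      write_report_json(psd_async, file.path(out_dir, nm, "misalignment_psd.json"))
    }
    cfg <- four_configurations()[[nm]]
    rows[[nm]] <- data.frame(
      line_trigger = if (cfg[["trigger"]] == "pll_x1") "PLL" else "Pos. feedback",
      sampling_clock = if (cfg[["clock"]] == "pll_locked") "PLL" else "Asynchronous",
      samples_rms = dx$rms,
      time_ns = dx$rms / run$rate * 1e9)
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  beat <- predict_beat_frequency(clock_spec("free_running", nominal_rate = run$rate,
                                            free_run_offset = p$free_run_offset),
                                 p$nominal_frequency)
  write_csv_lf(summary, file.path(out_dir, "summary.csv"))
  write_csv_lf(data.frame(predicted_beat_hz = beat),
               file.path(out_dir, "beat_prediction.csv"))
  list(summary = summary, psd_async = psd_async, predicted_beat_hz = beat)
}

experiment_fig8 <- function(config, out_dir) {
  p <- config$params
  f <- p$nominal_frequency
  S <- p$samples_per_cycle
  rate <- S * f
  spec <- scanner_spec(nominal_frequency = f, amplitude = p$amplitude,
                       mirror_jitter_rms = p$mirror_jitter_rms,
                       drift = drift_model("random_walk"),
                       feedback_noise = feedback_noise_spec(
                         white_rms = p$feedback_jitter_samples / rate))
  pll <- pll_config(p$loop_bandwidth, p$damping, multipliers = 1L)
  phant <- slit_for(p$amplitude, S, p$slit_width_samples, p$slit_psf_samples,
                    p$photon_scale, p$background)
  curves <- list()
  for (nm in c("fb_async", "pll_pll")) {
    cfg <- four_configurations()[[nm]]
    rec <- acquire_line_scan(spec, trigger_config(cfg[["trigger"]], S),
                             clock_spec(cfg[["clock"]], nominal_rate = rate),
                             phant, n_cycles = p$n_cycles, seed = config$seed,
                             pll = pll)
    curves[[nm]] <- averaging_broadening_curve(rec, p$frame_counts)
    write_report_json(curves[[nm]], file.path(out_dir, paste0("fwhm_curve_", nm, ".json")))
  }
  summary <- do.call(rbind, lapply(names(curves), function(nm) {
    cv <- curves[[nm]]
    data.frame(configuration = nm, frames = cv$frame_counts,
               fwhm_samples = cv$fwhm_mean,
               widening_vs_single = cv$widening_vs_single)
  }))
  write_csv_lf(summary, file.path(out_dir, "summary.csv"))
  list(summary = summary, curves = curves)
}
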