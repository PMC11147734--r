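# Shared fixtures: a scaled-down 12 kHz acquisition geometry (200 samples
# per cycle instead of 6700) keeps every simulated record small while
# preserving all timing mechanisms, which live in sample units.

FIX_F12 <- 12000
FIX_S <- 200L
FIX_RATE <- FIX_S * FIX_F12
FIX_AMP12 <- 5 * pi / 180
FIX_RPS <- FIX_AMP12 * 2 * pi / FIX_S  # radians per sample at scan center

quiet_spec_12k <- function(...) {
  scanner_spec(nominal_frequency = FIX_F12, amplitude = FIX_AMP12, ...)
}

# narrow slit (near-Gaussian image, FWHM ~ 6 samples) at high SNR
fix_slit <- function(photon_scale = 8000) {
  phantom_slit(center = 0, width = 0.5 * FIX_RPS, psf_sigma = 2.5 * FIX_RPS,
               photon_scale = photon_scale, background = 10)
}

# wider slit for FWHM-shape tests
fix_slit_wide <- function(photon_scale = 5000) {
  phantom_slit(center = 0, width = 4 * FIX_RPS, psf_sigma = 2 * FIX_RPS,
               photon_scale = photon_scale, background = 10)
}

fix_powder <- function(photon_scale = 2000) {
  phantom_powder(emitter_density = 40 / (2 * FIX_AMP12 * 4 * 3 * FIX_RPS),
                 emitter_sigma = 1.5 * FIX_RPS, psf_sigma = 2 * FIX_RPS,
                 photon_scale = photon_scale, background = 10)
}

fix_trigger <- function(source = "pll_x1") trigger_config(source, FIX_S)
fix_clock_pll <- function() clock_spec("pll_locked", FIX_RATE)
fix_clock_free <- function(offset = 7.3, phase = NULL) {
  clock_spec("free_running", FIX_RATE, free_run_offset = offset, phase = phase)
}

# sample RMS about the mean (the package-wide jitter definition)
rms_centered <- function(x) sqrt(mean((x - mean(x))^2))

# build a line_scan_record by hand (for metrology tests that need full
# control of the counts matrix)
synthetic_record <- function(counts, template = NULL, S = ncol(counts),
                             sample_rate = FIX_RATE, line_rate = FIX_F12) {
  structure(list(counts = counts, trigger_times = seq_len(nrow(counts)) / line_rate,
                 quant_error_samples = numeric(nrow(counts)),
                 injected_shift_samples = numeric(nrow(counts)),
                 template = if (is.null(template)) colMeans(counts) else template,
                 S = as.integer(S), sample_rate = sample_rate,
                 line_rate = line_rate, amplitude = FIX_AMP12,
                 phantom = list(kind = "synthetic"),
                 provenance = list(trigger_source = "synthetic",
                                   clock_mode = "synthetic")),
            class = "line_scan_record")
}
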