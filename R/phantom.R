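#' Imaging phantoms
#'
#' Synthetic targets evaluated in mirror-angle coordinates.  `phantom_slit`
#' is a fixed slit: a rectangular transmission window of angular `width`
#' convolved with a Gaussian system PSF (`psf_sigma`), the standard target
#' for line-trigger jitter metrology.  `phantom_powder` is a field of
#' point-like fluorescent emitters (static across scan cycles) giving
#' structured lines suitable for cross-correlation.  `phantom_point_grid`
#' describes a pulsed laser firing at a fixed `pulse_period` for
#' camera-frame acquisition; it has no angular intensity profile.
#'
#' @param center slit center angle in radians.
#' @param width slit angular width in radians.
#' @param psf_sigma Gaussian PSF sigma in radians.
#' @param photon_scale expected photon counts at an unobstructed peak.
#' @param background expected background counts per sample.
#' @return object of class `phantom`.
#' @export
phantom_slit <- function(center = 0, width, psf_sigma, photon_scale = 1000,
                         background = 10) {
  stopifnot(width > 0, psf_sigma > 0, photon_scale > 0, background >= 0)
  structure(list(kind = "slit", center = center, width = width,
                 psf_sigma = psf_sigma, photon_scale = photon_scale,
                 background = background),
            class = "phantom")
}

#' @rdname phantom_slit
#' @param emitter_density expected emitters per square radian of the sample
#'   plane; the line scan sees a strip of height `4 * psf_sigma`.
#' @param emitter_sigma intrinsic emitter size (radians).
#' @param extent_fraction fraction of the scan range populated with
#'   emitters (keeps structure away from the turnaround regions).
#' @export
phantom_powder <- function(emitter_density, emitter_sigma, psf_sigma,
                           photon_scale = 1000, background = 10,
                           extent_fraction = 0.85) {
  stopifnot(emitter_density >= 0, emitter_sigma > 0, psf_sigma > 0,
            extent_fraction > 0, extent_fraction <= 1)
  structure(list(kind = "powder", emitter_density = emitter_density,
                 emitter_sigma = emitter_sigma, psf_sigma = psf_sigma,
                 photon_scale = photon_scale, background = background,
                 extent_fraction = extent_fraction),
            class = "phantom")
}

#' @rdname phantom_slit
#' @param pulse_period laser pulse period in seconds (e.g. 100e-9 for a
#'   10 MHz pulsed laser).
#' @export
phantom_point_grid <- function(pulse_period = 100e-9, psf_sigma = 100e-6,
                               photon_scale = 1000, background = 2) {
  stopifnot(pulse_period > 0, psf_sigma > 0)
  structure(list(kind = "point_grid", pulse_period = pulse_period,
                 psf_sigma = psf_sigma, photon_scale = photon_scale,
                 background = background),
            class = "phantom")
}

## Draw the emitter field once per acquisition (substreamed) so that the
## phantom is static across cycles, as a real powder sample is.
realize_phantom <- function(phantom, amplitude, seed) {
  if (phantom$kind != "powder") return(phantom)
  half <- amplitude * phantom$extent_fraction
  strip <- 4 * phantom$psf_sigma
  lambda <- phantom$emitter_density * 2 * half * strip
  with_substream(seed, "phantom", {
    n <- max(3L, stats::rpois(1L, lambda))
    phantom$emitters <- data.frame(
      angle = stats::runif(n, -half, half),
      amp = stats::runif(n, 0.3, 1) * phantom$photon_scale)
  })
  phantom
}

## Expected photon counts at fast-axis angle(s) theta.
phantom_expected <- function(phantom, theta) {
  switch(phantom$kind,
         slit = {
           s <- phantom$psf_sigma
           phantom$background + phantom$photon_scale *
             (stats::pnorm((theta - phantom$center + phantom$width / 2) / s) -
              stats::pnorm((theta - phantom$center - phantom$width / 2) / s))
         },
         powder = {
           if (is.null(phantom$emitters)) {
             stop("phantom_expected: powder phantom must be realized first (internal error)")
           }
           s2 <- phantom$psf_sigma^2 + phantom$emitter_sigma^2
           v <- rep(phantom$background, length(theta))
           for (i in seq_len(nrow(phantom$emitters))) {
             v <- v + phantom$emitters$amp[i] *
               exp(-(theta - phantom$emitters$angle[i])^2 / (2 * s2))
           }
           v
         },
         stop("phantom_expected: phantom kind '", phantom$kind,
              "' has no angular intensity profile"))
}
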