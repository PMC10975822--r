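# Forward model: incoherent imaging through a thin diffuser modelled as a
# random phase screen. The PSF is the squared modulus of the Fourier transform
# of (circular aperture x unit-modulus phasor), so the speckle frame is the
# object convolved (circularly) with a fully developed speckle PSF.

#' Physical and sampling parameters of the scattering imaging system
#'
#' @param wavelength illumination wavelength (m).
#' @param object_distance object-to-diffuser distance u (m).
#' @param diffuser_camera_distance diffuser-to-camera distance d (m).
#' @param diffuser_thickness scattering layer thickness l (m).
#' @param aperture_diameter iris diameter D behind the diffuser (m).
#' @param sensor_shape integer `c(rows, cols)`, each >= 64.
#' @param pixel_pitch sensor pixel size (m).
#' @param seed integer seed driving all stochastic generation.
#' @return a `scene_config` list.
#' @export
scene_config <- function(wavelength = 632.8e-9,
                         object_distance = 0.64,
                         diffuser_camera_distance = 0.085,
                         diffuser_thickness = 1e-3,
                         aperture_diameter = 2.5e-3,
                         sensor_shape = c(2048L, 2048L),
                         pixel_pitch = 2.4e-6,
                         seed = 1L) {
  if (length(sensor_shape) == 1) sensor_shape <- rep(sensor_shape, 2)
  lens <- c(wavelength, object_distance, diffuser_camera_distance,
            diffuser_thickness, aperture_diameter, pixel_pitch)
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    stop("all physical lengths must be positive and finite")
  }
  if (any(sensor_shape < 64)) stop("sensor_shape must be >= 64 in each dimension")
  structure(list(wavelength = wavelength,
                 object_distance = object_distance,
                 diffuser_camera_distance = diffuser_camera_distance,
                 diffuser_thickness = diffuser_thickness,
                 aperture_diameter = aperture_diameter,
                 sensor_shape = as.integer(sensor_shape),
                 pixel_pitch = pixel_pitch,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Preset scene configurations
#'
#' `"fig1"` mirrors the simulation conditions of the reference setup
#' (632.8 nm source, 2048 x 2048 sensor, 2.4 um pitch); `"fast"` is a
#' desk-scale 512 x 512 variant whose iris is chosen so the speckle grain
#' spans ~8 px: with a frame only 1/16 the reference area, keeping the
#' grain count per sub-speckle low preserves the bispectrum ensemble
#' signal-to-noise (which scales as sqrt(N/n) in the total grain count N
#' and grains per tile n) while the ~8 px diffraction limit stays well
#' below the default 32 px object support.
#'
#' @param name `"fast"` or `"fig1"`.
#' @param seed integer seed.
#' @return a [scene_config()].
#' @export
preset_config <- function(name = c("fast", "fig1"), seed = 1L) {
  name <- match.arg(name)
  switch(name,
    fig1 = scene_config(seed = seed),
    fast = scene_config(sensor_shape = c(512L, 512L),
                        aperture_diameter = 1.5e-4,
                        seed = seed))
}

#' Generate a uniform random phase screen
#'
#' i.i.d. phases uniform on `[0, 2*pi)`; bit-identical for a fixed seed.
#'
#' @param shape integer `c(rows, cols)`.
#' @param seed integer seed.
#' @return a `phase_screen` with a `phases` matrix.
#' @export
make_phase_screen <- function(shape, seed = 1L) {
  if (length(shape) == 1) shape <- rep(shape, 2)
  if (any(shape < 1)) stop("shape must be positive")
  rng <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    matrix(stats::runif(prod(shape), 0, 2 * pi), shape[1], shape[2])
  })
  structure(list(phases = rng, seed = as.integer(seed)), class = "phase_screen")
}

#' Incoherent speckle point spread function from a phase screen
#'
#' PSF = |FT(aperture mask x exp(i phase))|^2, centered and normalized to unit
#' sum. The circular aperture radius in pixels is
#' `aperture_diameter / (2 * pixel_pitch)`.
#'
#' @param screen a [make_phase_screen()] result with shape matching
#'   `config$sensor_shape`.
#' @param config a [scene_config()].
#' @return a `psf` with nonnegative `intensities` summing to 1.
#' @export
make_incoherent_psf <- function(screen, config) {
  ph <- screen$phases
  if (!all(dim(ph) == config$sensor_shape)) {
    stop("phase screen shape must match config$sensor_shape")
  }
  r_px <- config$aperture_diameter / (2 * config$pixel_pitch)
  if (2 * r_px > min(dim(ph))) stop("aperture larger than the simulation grid")
  nr <- nrow(ph); nc <- ncol(ph)
  yy <- seq_len(nr) - (nr %/% 2 + 1)
  xx <- seq_len(nc) - (nc %/% 2 + 1)
  mask <- outer(yy^2, xx^2, "+") <= r_px^2
  pupil <- mask * exp(1i * ph)
  field <- ft2c(pupil)
  psf <- Re(field * Conj(field))
  psf <- psf / sum(psf)
  structure(list(intensities = psf, aperture_radius_px = r_px), class = "psf")
}

#' Render a speckle frame (object convolved with the speckle PSF)
#'
#' Circular convolution of the object with the PSF; within the memory-effect
#' field of view every object point contributes a shifted copy of the same
#' speckle pattern. Optional Poisson shot noise with a given expected total
#' photon count.
#'
#' @param object an [make_object()] result (or plain nonnegative matrix).
#' @param psf a [make_incoherent_psf()] result (or plain matrix).
#' @param photon_budget expected total photon count, or `NULL` for noiseless.
#' @param seed seed for the shot noise draw (required when `photon_budget`
#'   is given).
#' @return a `speckle_frame` with nonnegative `intensities`.
#' @export
render_speckle <- function(object, psf, photon_budget = NULL, seed = 1L) {
  o <- if (inherits(object, "object_image")) object$intensities else object
  s <- if (inherits(psf, "psf")) psf$intensities else psf
  if (!all(dim(o) == dim(s))) stop("object and PSF grids must match")
  frame <- Re(stats::fft(stats::fft(o) * stats::fft(s), inverse = TRUE)) / length(o)
  frame[frame < 0] <- 0  # clip FFT round-off
  if (!is.null(photon_budget)) {
    tot <- sum(frame)
    if (tot <= 0) stop("cannot apply shot noise to an all-zero frame")
    lam <- frame * (photon_budget / tot)
    frame <- local({
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
      matrix(stats::rpois(length(lam), lam), nrow(lam), ncol(lam))
    })
  }
  structure(list(intensities = frame, provenance = "simulated"),
            class = "speckle_frame")
}

#' Simulate a full scene in one call
#'
#' Convenience wrapper: object, phase screen, PSF and speckle frame from one
#' [scene_config()]. The object support defaults to a small fraction of the
#' frame so the memory-effect assumption holds.
#'
#' @param config a [scene_config()].
#' @param glyph glyph id for [make_object()].
#' @param support object height in pixels; default `min(sensor)/16`.
#' @param photon_budget optional expected photon count for shot noise.
#' @return list with `object`, `screen`, `psf`, `frame`.
#' @export
simulate_speckle <- function(config, glyph = "5", support = NULL,
                             photon_budget = NULL) {
  if (is.null(support)) support <- as.integer(min(config$sensor_shape) / 16)
  obj <- make_object(glyph, config$sensor_shape, support)
  scr <- make_phase_screen(config$sensor_shape, config$seed)
  psf <- make_incoherent_psf(scr, config)
  frame <- render_speckle(obj, psf, photon_budget = photon_budget,
                          seed = config$seed + 1L)
  list(object = obj, screen = scr, psf = psf, frame = frame, config = config)
}

#' Memory-effect field-of-view limit
#'
#' Maximum field of view of the scattering imaging system,
#' `delta_x = u * lambda / (pi * l)`.
#'
#' @param config a [scene_config()].
#' @return length in meters.
#' @export
fov_limit <- function(config) {
  if (config$diffuser_thickness <= 0) stop("diffuser thickness must be positive")
  config$object_distance * config$wavelength / (pi * config$diffuser_thickness)
}

#' Diffraction-limited resolution on the image plane
#'
#' Minimum resolvable interval `delta = 1.22 * lambda * d / D` for the
#' iris-limited pupil.
#'
#' @param config a [scene_config()].
#' @return length in meters.
#' @export
diffraction_limit <- function(config) {
  if (config$aperture_diameter <= 0) stop("aperture diameter must be positive")
  1.22 * config$wavelength * config$diffuser_camera_distance / config$aperture_diameter
}

#' @export
print.speckle_frame <- function(x, ...) {
  cat(sprintf("<speckle_frame> %d x %d, %s, mean %.4g\n",
              nrow(x$intensities), ncol(x$intensities), x$provenance,
              mean(x$intensities)))
  invisible(x)
}
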