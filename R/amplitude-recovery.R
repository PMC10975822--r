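# Fourier amplitude of the hidden object from a single speckle frame.
# Because the frame is the object convolved with a speckle PSF whose
# autocorrelation is sharply peaked, the speckle autocorrelation equals the
# object autocorrelation plus a background pedestal; by the Wiener-Khinchin
# theorem the windowed autocorrelation then yields the object power spectrum.

#' Speckle autocorrelation (Wiener-Khinchin route)
#'
#' Subtracts the frame mean (removing the background pedestal / DC term), then
#' computes the circular autocorrelation as the inverse FT of the squared FT
#' magnitude, shifted so zero lag is at the grid center.
#'
#' @param frame a `speckle_frame` or nonnegative matrix.
#' @return an `autocorrelation`: list with `values` (zero lag centered),
#'   `background_estimate` (the subtracted mean) and `windowed` flag.
#' @export
autocorrelate <- function(frame) {
  x <- if (inherits(frame, "speckle_frame")) frame$intensities else frame
  if (!all(is.finite(x))) stop("frame must be finite")
  if (all(x == 0)) stop("cannot autocorrelate an all-zero frame")
  bg <- mean(x)
  x0 <- x - bg
  F <- stats::fft(x0)
  ac <- Re(stats::fft(F * Conj(F), inverse = TRUE)) / length(x0)
  structure(list(values = fftshift(ac), background_estimate = bg,
                 windowed = FALSE, taper = "none"),
            class = "autocorrelation")
}

# Radially symmetric taper profiles on normalized radius r (r = 1 at the
# window edge along the axes).
taper_profile <- function(r, kind, tukey_alpha = 0.3, gauss_sigma = 0.5) {
  switch(kind,
    rect = rep(1, length(r)),
    tukey = {
      w <- numeric(length(r))
      flat <- r <= 1 - tukey_alpha
      edge <- r > 1 - tukey_alpha & r <= 1
      w[flat] <- 1
      w[edge] <- 0.5 * (1 + cos(pi * (r[edge] - (1 - tukey_alpha)) / tukey_alpha))
      w
    },
    hann = ifelse(r <= 1, 0.5 * (1 + cos(pi * r)), 0),
    gaussian = exp(-r^2 / (2 * gauss_sigma^2)),
    stop("unknown taper '", kind, "'"))
}

#' Restrict the autocorrelation to its informative central window
#'
#' The object occupies only a small central part of the full-frame speckle
#' autocorrelation; keeping only the center suppresses the high-frequency
#' noise an excessive sampling bandwidth would introduce. The central
#' `(2*half_width+1)^2` region is extracted and multiplied by a radially
#' symmetric taper.
#'
#' @param ac an [autocorrelate()] result.
#' @param half_width window half-width in pixels; window is
#'   `(2*half_width+1)^2`, must fit in the frame.
#' @param taper `"tukey"` (default), `"gaussian"`, `"hann"` or `"rect"`.
#' @param tukey_alpha cosine-edge fraction of the Tukey taper.
#' @return a windowed `autocorrelation` on the small grid.
#' @export
window_autocorrelation <- function(ac, half_width = 150L,
                                   taper = c("tukey", "gaussian", "hann", "rect"),
                                   tukey_alpha = 0.3) {
  taper <- match.arg(taper)
  w <- 2L * as.integer(half_width) + 1L
  if (w > min(dim(ac$values))) stop("half_width too large for this frame")
  win <- center_crop(ac$values, w)
  d <- seq_len(w) - (half_width + 1L)
  r <- sqrt(outer(d^2, d^2, "+")) / half_width
  win <- win * taper_profile(r, taper, tukey_alpha)
  structure(list(values = win, background_estimate = ac$background_estimate,
                 windowed = TRUE, taper = taper),
            class = "autocorrelation")
}

#' Object Fourier amplitude from the windowed autocorrelation
#'
#' FT of the windowed autocorrelation is the object's power spectrum (up to
#' the real, nonnegative transfer term); its real part is clamped at zero and
#' square-rooted. DC sits at the grid center.
#'
#' @param ac a windowed, centered [autocorrelation].
#' @return a `fourier_amplitude`: `magnitudes` matrix (DC centered) with a
#'   `clamped_fraction` diagnostic (share of negative power-spectrum pixels).
#' @export
fourier_amplitude <- function(ac) {
  ps <- Re(ft2c(ac$values))
  neg <- mean(ps < 0)
  ps[ps < 0] <- 0
  structure(list(magnitudes = sqrt(ps), clamped_fraction = neg),
            class = "fourier_amplitude")
}

#' @export
print.autocorrelation <- function(x, ...) {
  cat(sprintf("<autocorrelation> %d x %d, %s, background %.4g\n",
              nrow(x$values), ncol(x$values),
              if (x$windowed) paste0("windowed (", x$taper, ")") else "full frame",
              x$background_estimate))
  invisible(x)
}

#' @export
print.fourier_amplitude <- function(x, ...) {
  cat(sprintf("<fourier_amplitude> %d x %d, clamped fraction %.3f\n",
              nrow(x$magnitudes), ncol(x$magnitudes), x$clamped_fraction))
  invisible(x)
}
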