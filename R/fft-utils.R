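# Centered-FFT helpers shared across the amplitude and bispectrum paths.
# Convention: "centered" grids place the origin (zero lag / DC) at index
# floor(n/2)+1 along each axis, which is the exact center of odd-sized grids.

circshift_idx <- function(n, k) ((seq_len(n) - 1 - k) %% n) + 1

#' Shift the zero-frequency (or zero-lag) component to the grid center
#'
#' @param x numeric or complex vector or matrix.
#' @return `x` circularly shifted so index 1 moves to `floor(n/2)+1`.
#' @export
fftshift <- function(x) {
  if (is.matrix(x)) {
    x[circshift_idx(nrow(x), nrow(x) %/% 2), circshift_idx(ncol(x), ncol(x) %/% 2)]
  } else {
    x[circshift_idx(length(x), length(x) %/% 2)]
  }
}

#' Inverse of [fftshift()]
#' @param x numeric or complex vector or matrix.
#' @return `x` with the centered origin moved back to index 1.
#' @export
ifftshift <- function(x) {
  if (is.matrix(x)) {
    x[circshift_idx(nrow(x), -(nrow(x) %/% 2)), circshift_idx(ncol(x), -(ncol(x) %/% 2))]
  } else {
    x[circshift_idx(length(x), -(length(x) %/% 2))]
  }
}

# 2D FFT with the spatial origin and DC both at the grid center.
ft2c <- function(x) fftshift(stats::fft(ifftshift(x)))

# Inverse of ft2c; returns a complex matrix (caller takes Re as needed).
ift2c <- function(F) fftshift(stats::fft(ifftshift(F), inverse = TRUE)) / length(F)

# Maximum normalized cross-correlation between two equally sized images over
# all circular shifts (zero-mean, unit-norm; computed via FFT).
ncc_best_shift <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  a0 <- a - mean(a); b0 <- b - mean(b)
  na <- sqrt(sum(a0^2)); nb <- sqrt(sum(b0^2))
  if (na == 0 || nb == 0) stop("ncc undefined for a constant image")
  xc <- Re(stats::fft(stats::fft(a0) * Conj(stats::fft(b0)), inverse = TRUE)) / length(a0)
  i <- which.max(xc)
  list(ncc = max(xc) / (na * nb),
       shift = c((i - 1) %% nrow(a), (i - 1) %/% nrow(a)))
}

#' Alignment-invariant normalized cross-correlation
#'
#' Maximum zero-mean normalized cross-correlation between two images over all
#' circular shifts. Used as the reconstruction fidelity score (1 = identical up
#' to shift and scale).
#'
#' @param a,b numeric matrices of identical dimensions.
#' @return scalar in `[-1, 1]`.
#' @export
ncc_aligned <- function(a, b) ncc_best_shift(a, b)$ncc

# Circularly shift matrix by (dr, dc) so that x_new[i,j] = x[i-dr, j-dc].
circshift2 <- function(x, dr, dc) {
  x[circshift_idx(nrow(x), dr), circshift_idx(ncol(x), dc)]
}

# Central crop of size w x w (w odd) about the centered origin.
center_crop <- function(x, w) {
  stopifnot(w <= min(dim(x)))
  cr <- nrow(x) %/% 2 + 1
  cc <- ncol(x) %/% 2 + 1
  h <- (w - 1) %/% 2
  x[(cr - h):(cr + h), (cc - h):(cc + h)]
}

# Embed a small matrix centrally into a larger zero canvas.
center_embed <- function(x, dims) {
  out <- matrix(0, dims[1], dims[2])
  cr <- dims[1] %/% 2 + 1
  cc <- dims[2] %/% 2 + 1
  hr <- nrow(x) %/% 2
  hc <- ncol(x) %/% 2
  r0 <- cr - hr; c0 <- cc - hc
  out[r0:(r0 + nrow(x) - 1), c0:(c0 + ncol(x) - 1)] <- x
  out
}

wrap_phase <- function(p) Arg(exp(1i * p))
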