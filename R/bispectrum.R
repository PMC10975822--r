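# Truncated 1D bispectrum and recursive phase-closure recovery.
# The bispectrum B(f1,f2) = X(f1) X(f2) X*(f1+f2) is translation-invariant and
# its ensemble mean over sub-speckles factors into the object bispectrum times
# a *real* transfer term, so the averaged bispectrum phase is the object's
# phase closure: phi_B(f1,f2) = phi(f1) + phi(f2) - phi(f1+f2). Retaining only
# the low-frequency index box f <= (1-C)*M (truncation factor C) discards the
# redundant high-frequency elements that dominate the computation.

#' Bispectrum truncation scheme
#'
#' Retains the index box `0 <= f1, f2 <= f_max` with
#' `f_max = floor((1-C)*M)` (capped at `M-1`).
#'
#' @param C truncation factor in `[0, 1)`: larger C discards more data.
#' @param M length of the projected 1D signals.
#' @return a `truncation_scheme` with `C`, `M`, `f_max`.
#' @export
truncation_scheme <- function(C, M) {
  if (!(C >= 0 && C < 1)) stop("truncation factor C must be in [0, 1)")
  M <- as.integer(M)
  if (M < 2) stop("M must be >= 2")
  f_max <- min(M - 1L, as.integer(floor((1 - C) * M)))
  structure(list(C = C, M = M, f_max = f_max), class = "truncation_scheme")
}

#' Fraction of bispectrum elements retained under truncation
#'
#' `(f_max+1)^2 / M^2`; the complementary data reduction is `1 - fraction`.
#'
#' @param scheme a [truncation_scheme()].
#' @return scalar in `(0, 1]`.
#' @export
retained_fraction <- function(scheme) {
  (scheme$f_max + 1)^2 / scheme$M^2
}

#' Element count of the full 4D bispectrum of a P x P image
#'
#' Direct bispectrum computation of a 2D image is 4D with `P^4` elements
#' (about 4e9 already at P = 256), which is what the Radon-projection route
#' avoids.
#'
#' @param P image side in pixels.
#' @return `P^4` as a double.
#' @export
full_bispectrum_count <- function(P) {
  if (P < 1) stop("P must be >= 1")
  as.numeric(P)^4
}

#' Truncated bispectrum of a 1D real signal
#'
#' `B(f1,f2) = X(f1) X(f2) Conj(X(f1+f2))` over the retained index box,
#' with `X` the forward DFT of `x`; `f1+f2` uses the periodic DFT index.
#'
#' @param x real vector of length `scheme$M`.
#' @param scheme a [truncation_scheme()].
#' @return complex `(f_max+1) x (f_max+1)` matrix, rows/cols indexed by
#'   `f1, f2 = 0..f_max`.
#' @export
truncated_bispectrum <- function(x, scheme) {
  if (!all(is.finite(x))) stop("signal must be finite")
  if (length(x) != scheme$M) stop("signal length does not match scheme M")
  X <- stats::fft(x)
  f <- 0:scheme$f_max
  Xf <- X[f + 1]
  s <- outer(f, f, "+") %% scheme$M
  B <- outer(Xf, Xf) * Conj(X[s + 1])
  dimnames(B) <- NULL
  B
}

#' Average per-tile bispectra (angle-wise spatial ensemble mean)
#'
#' Arithmetic mean of complex bispectra across sub-speckle tiles, the spatial
#' stand-in for the multi-frame temporal average of astronomical speckle
#' imaging. Accepts a list of matrices (one angle) or a list of
#' `(f+1, f+1, A)` arrays (all angles per tile).
#'
#' @param bispectra list over tiles of complex matrices or arrays with
#'   identical dimensions.
#' @param scheme the common [truncation_scheme()].
#' @param angles optional angle vector carried through.
#' @return a `truncated_bispectrum` object: `values` array
#'   `(f_max+1, f_max+1, A)`, `scheme`, `angles`, `n_averaged`.
#' @export
average_bispectra <- function(bispectra, scheme, angles = NULL) {
  if (length(bispectra) < 1) stop("need at least one tile bispectrum")
  d1 <- dim(bispectra[[1]])
  for (b in bispectra) {
    if (!identical(dim(b), d1)) stop("mismatched bispectrum schemes across tiles")
  }
  acc <- Reduce(`+`, bispectra) / length(bispectra)
  if (length(d1) == 2) acc <- array(acc, c(d1, 1L))
  if (is.null(angles)) angles <- seq_len(dim(acc)[3]) - 1
  structure(list(values = acc, scheme = scheme, angles = angles,
                 n_averaged = length(bispectra)),
            class = "truncated_bispectrum")
}

#' Tile-averaged truncated bispectrum of a sinogram
#'
#' Computes the truncated bispectrum of every tile's projection at every
#' angle and accumulates the per-angle mean incrementally (memory stays
#' independent of the tile count).
#'
#' @param sino a [radon_project()] sinogram.
#' @param scheme a [truncation_scheme()] with `M = sino$M`.
#' @return a `truncated_bispectrum` (see [average_bispectra()]), with a
#'   `grain_count_per_tile` diagnostic (speckle grains per tile, estimated
#'   from the tile autocorrelation area).
#' @export
speckle_bispectrum <- function(sino, scheme) {
  if (scheme$M != sino$M) stop("scheme M does not match sinogram M")
  A <- length(sino$angles)
  n <- dim(sino$projections)[3]
  nf <- scheme$f_max + 1L
  acc <- array(0i, c(nf, nf, A))
  for (k in seq_len(n)) {
    for (a in seq_len(A)) {
      acc[, , a] <- acc[, , a] + truncated_bispectrum(sino$projections[, a, k], scheme)
    }
  }
  structure(list(values = acc / n, scheme = scheme, angles = sino$angles,
                 n_averaged = n),
            class = "truncated_bispectrum")
}

#' Recursive phase-closure recovery of one angle's 1D Fourier phase
#'
#' Seeds `phase(0) = phase(1) = 0` (absolute position is not recoverable and
#' is not needed for the object's structure), then for each
#' `f = 2..f_reachable` phasor-averages the closure estimates
#' `phase(f1) + phase(f2) - arg B(f1, f2)` over all retained pairs
#' `f1 + f2 = f`, `1 <= f1 <= f2`. With `weights = "modulus"` (default) each
#' closure phasor is weighted by `|B(f1,f2)|`, down-weighting elements whose
#' averaged bispectrum is noise-dominated; `"none"` gives the plain
#' unit-phasor sum. `f_reachable = min(2*f_max, floor(M/2))`; phases beyond
#' it are set to 0.
#'
#' @param avg a `truncated_bispectrum`.
#' @param angle angle index (1-based) into `avg$angles`.
#' @param weights `"modulus"` or `"none"`.
#' @return a `radial_phase`: `phase` vector over `f = 0..f_reachable`
#'   (radians, wrapped), plus `angle_deg`, `f_reachable`, `M`.
#' @export
recover_phase_recursive <- function(avg, angle = 1L,
                                    weights = c("modulus", "none")) {
  weights <- match.arg(weights)
  sch <- avg$scheme
  B <- avg$values[, , angle]
  argB <- Arg(B)
  modB <- Mod(B)
  f_reach <- min(2L * sch$f_max, sch$M %/% 2L)
  ph <- numeric(f_reach + 1L)  # ph[f+1] = phase at frequency f
  for (f in seq_len(f_reach)[-1]) {
    f1 <- seq_len(f %/% 2L)
    f2 <- f - f1
    ok <- f1 <= sch$f_max & f2 <= sch$f_max
    f1 <- f1[ok]; f2 <- f2[ok]
    if (length(f1) == 0) { ph[f + 1L] <- 0; next }
    idx <- cbind(f1 + 1L, f2 + 1L)
    w <- if (weights == "modulus") modB[idx] else rep(1, length(f1))
    z <- sum(w * exp(1i * (ph[f1 + 1L] + ph[f2 + 1L] - argB[idx])))
    if (Mod(z) < .Machine$double.eps * sum(w)) {
      warning("zero-magnitude phasor sum at f = ", f, "; phase set to 0")
      ph[f + 1L] <- 0
    } else {
      ph[f + 1L] <- Arg(z)
    }
  }
  structure(list(phase = ph, angle_deg = avg$angles[angle],
                 f_reachable = f_reach, M = sch$M),
            class = "radial_phase")
}

#' Recover all angles' radial phases
#'
#' @param avg a `truncated_bispectrum`.
#' @param weights passed to [recover_phase_recursive()].
#' @return matrix `(f_reachable+1) x A`; column a is the phase along angle a.
#' @export
recover_phases <- function(avg, weights = c("modulus", "none")) {
  weights <- match.arg(weights)
  A <- dim(avg$values)[3]
  cols <- lapply(seq_len(A),
                 function(a) recover_phase_recursive(avg, a, weights)$phase)
  do.call(cbind, cols)
}

#' Align per-ray phase gauges to a common object centering
#'
#' Each ray's recursion fixes its own gauge (`phase(1) = 0`), which amounts
#' to re-centering that projection independently; residual per-ray linear
#' ramps then misregister the rays in 2D. This removes each ray's
#' amplitude-weighted best-fit linear ramp (estimated wrap-safely from phase
#' increments in phasor space), which places every projection's centroid at
#' the origin -- a gauge that is consistent across angles because projection
#' centroids of one object all derive from its single 2D centroid.
#'
#' @param radial `(F+1) x A` matrix of radial phases.
#' @param angles angles in degrees, length A.
#' @param amplitude a [fourier_amplitude()] result (or matrix, DC centered)
#'   supplying the per-ray weights.
#' @param freq_scale 1D frequency units per amplitude-grid pixel
#'   (`M / grid_size`).
#' @return the re-gauged `(F+1) x A` phase matrix.
#' @export
align_ray_gauges <- function(radial, angles, amplitude, freq_scale = 1) {
  amp <- if (inherits(amplitude, "fourier_amplitude")) amplitude$magnitudes else amplitude
  W <- nrow(amp)
  cen <- W %/% 2 + 1
  f <- 0:(nrow(radial) - 1)
  r <- f / freq_scale
  for (a in seq_along(angles)) {
    th <- angles[a] * pi / 180
    ii <- pmin(W, pmax(1, round(cen + r * sin(th))))
    jj <- pmin(W, pmax(1, round(cen + r * cos(th))))
    wts <- amp[cbind(ii, jj)]
    ph <- radial[, a]
    inc <- ph[-1] - ph[-length(ph)]
    wi <- pmin(wts[-1], wts[-length(wts)])
    slope <- Arg(sum(wi * exp(1i * inc)))
    radial[, a] <- wrap_phase(ph - slope * f)
  }
  radial
}

#' @export
print.truncated_bispectrum <- function(x, ...) {
  cat(sprintf("<truncated_bispectrum> C = %.2f, M = %d, f_max = %d, %d angle(s), N = %d tiles\n",
              x$scheme$C, x$scheme$M, x$scheme$f_max, dim(x$values)[3], x$n_averaged))
  invisible(x)
}

#' @export
print.truncation_scheme <- function(x, ...) {
  cat(sprintf("<truncation_scheme> C = %.2f, M = %d, f_max = %d: retain %d of %d elements (%.1f%% reduction)\n",
              x$C, x$M, x$f_max, (x$f_max + 1)^2, x$M^2,
              100 * (1 - retained_fraction(x))))
  invisible(x)
}
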