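# Polar-to-Cartesian assembly of the object's 2D Fourier phase. By the
# projection-slice theorem, the 1D FT of the projection at angle theta is the
# central slice of the 2D FT along that direction, so each recovered radial
# phase populates one Fourier-domain ray. Cartesian grid points are filled by
# phasor interpolation (interpolate exp(i*phi), then take the argument, which
# is immune to 2*pi wraps) between the two nearest rays and radii; Hermitian
# antisymmetry phi(-k) = -phi(k) is enforced exactly by construction from the
# upper half-plane.

#' Assemble the 2D Fourier phase from per-angle radial phases
#'
#' @param radial matrix `(F+1) x A` of radial phases (`f = 0..F` down rows,
#'   one column per angle), or a list of `radial_phase` objects.
#' @param angles angles in degrees, all in `[0, 180)`, at least 2 distinct.
#' @param grid_size odd side length of the output phase grid (the amplitude
#'   window geometry).
#' @param freq_scale radial 1D frequency units per output grid pixel:
#'   `M / grid_size` when projections of length `M` feed a `grid_size`
#'   amplitude window. Default 1 (same grid).
#' @return a `fourier_phase2d`: `phase` matrix (radians, DC centered at
#'   `(grid_size%/%2+1)`), exactly antisymmetric, `phase[DC] = 0`.
#' @export
assemble_phase_2d <- function(radial, angles, grid_size, freq_scale = 1) {
  if (is.list(radial) && !is.matrix(radial)) {
    angles <- vapply(radial, function(r) r$angle_deg, numeric(1))
    radial <- do.call(cbind, lapply(radial, function(r) r$phase))
  }
  if (length(unique(angles)) < 2) stop("need at least 2 distinct angles")
  if (grid_size %% 2 != 1) stop("grid_size must be odd (DC at the exact center)")
  if (any(angles < 0 | angles >= 180)) stop("angles must lie in [0, 180)")
  Fmax <- nrow(radial) - 1L
  A <- length(angles)

  # Extended ray table over [0, 360): theta + 180 carries the negated phase
  # (Hermitian symmetry of a real object).
  ord <- order(angles)
  ext_ang <- c(angles[ord], angles[ord] + 180)
  ext_col <- c(ord, ord)
  ext_sgn <- c(rep(1, A), rep(-1, A))

  h <- grid_size %/% 2
  cen <- h + 1L
  # Upper half-plane: ky > 0, plus the ky = 0, kx > 0 half-axis.
  out <- matrix(0, grid_size, grid_size)
  kx <- rep(seq_len(grid_size) - cen, each = grid_size)
  ky <- rep(seq_len(grid_size) - cen, times = grid_size)
  half <- which(ky > 0 | (ky == 0 & kx > 0))
  kxh <- kx[half]; kyh <- ky[half]
  r <- sqrt(kxh^2 + kyh^2) * freq_scale
  th <- (atan2(kyh, kxh) * 180 / pi) %% 360

  inb <- r <= Fmax
  phs <- numeric(length(half))
  if (any(inb)) {
    ri <- r[inb]; ti <- th[inb]
    # bracketing rays (circular over the extended 360-degree table)
    hi <- findInterval(ti, ext_ang)            # 0 when below first ray
    lo <- ifelse(hi == 0, 2L * A, hi)
    up <- ifelse(hi == 2L * A | hi == 0L, 1L, hi + 1L)
    a_lo <- ext_ang[lo]; a_up <- ext_ang[up]
    gap <- (a_up - a_lo) %% 360
    gap[gap == 0] <- 360
    dlo <- (ti - a_lo) %% 360
    w_up <- dlo / gap
    w_lo <- 1 - w_up
    r0 <- floor(ri); r1 <- pmin(Fmax, r0 + 1)
    wr1 <- ri - r0
    wr0 <- 1 - wr1
    val <- function(ray_idx, sgn, f) {
      # phase at integer radius f on extended ray; f is a vector
      exp(1i * sgn * radial[cbind(f + 1, ext_col[ray_idx])])
    }
    z <- w_lo * wr0 * val(lo, ext_sgn[lo], r0) +
         w_lo * wr1 * val(lo, ext_sgn[lo], r1) +
         w_up * wr0 * val(up, ext_sgn[up], r0) +
         w_up * wr1 * val(up, ext_sgn[up], r1)
    p <- Arg(z)
    p[Mod(z) < 1e-12] <- 0
    p[ri == 0] <- 0
    phs[inb] <- p
  }
  out[half] <- phs
  # Mirror with exact antisymmetry (-k is the index-reversed point); DC stays 0.
  out <- out - out[grid_size:1, grid_size:1]
  structure(list(phase = out, grid_size = grid_size, freq_scale = freq_scale,
                 angles = angles),
            class = "fourier_phase2d")
}

#' @export
print.fourier_phase2d <- function(x, ...) {
  cat(sprintf("<fourier_phase2d> %d x %d, %d angles, freq scale %.3f\n",
              x$grid_size, x$grid_size, length(x$angles), x$freq_scale))
  invisible(x)
}
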