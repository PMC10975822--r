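# Sub-speckle tiling and Radon projection. Cropping a single frame into many
# tiles replaces the multi-frame temporal ensemble of astronomical speckle
# interferometry with a spatial ensemble; projecting each tile to 1D signals
# at a fan of angles reduces the 4D image bispectrum to a set of cheap 1D
# bispectra (one per angle), linked back to 2D via the projection-slice
# theorem.

#' Crop a speckle frame into sub-speckle tiles
#'
#' Raster-order `K x K` tiles fully inside the frame;
#' `N = floor((H-K)/stride+1) * floor((W-K)/stride+1)`.
#'
#' @param frame a `speckle_frame` or matrix.
#' @param K tile side in pixels.
#' @param stride step between tile origins; default `K` (non-overlapping).
#' @return a `subspeckle_stack`: `tiles` array `(K, K, N)`, `origins`
#'   (N x 2 top-left pixel coordinates), `K`.
#' @export
crop_subspeckles <- function(frame, K, stride = K) {
  x <- if (inherits(frame, "speckle_frame")) frame$intensities else frame
  K <- as.integer(K); stride <- as.integer(stride)
  if (K > min(dim(x))) stop("tile size K exceeds the frame")
  if (stride < 1) stop("stride must be >= 1")
  r0 <- seq(1L, nrow(x) - K + 1L, by = stride)
  c0 <- seq(1L, ncol(x) - K + 1L, by = stride)
  n <- length(r0) * length(c0)
  tiles <- array(0, c(K, K, n))
  origins <- matrix(0L, n, 2)
  k <- 1L
  for (i in r0) for (j in c0) {  # raster order: rows outer, cols inner
    tiles[, , k] <- x[i:(i + K - 1L), j:(j + K - 1L)]
    origins[k, ] <- c(i, j)
    k <- k + 1L
  }
  structure(list(tiles = tiles, origins = origins, K = K, apodized = FALSE),
            class = "subspeckle_stack")
}

#' Apodize sub-speckle tiles with a Gaussian window
#'
#' Each tile first has its mean (the DC pedestal of the nonnegative speckle)
#' subtracted, is then multiplied by a centered 2D Gaussian with
#' `sigma = sigma_fraction * K`, and is finally re-centered to exactly zero
#' mean. Removing the pedestal *before* windowing matters: windowing the raw
#' tile leaves a deterministic `mean x (Gaussian - its mean)` term common to
#' every tile, whose 0/pi-phase bispectrum otherwise dominates the
#' low-frequency closure statistics. Degenerate tiles whose windowed energy
#' falls below `1e-6` of the median tile energy are dropped with a warning.
#'
#' @param stack a [crop_subspeckles()] result.
#' @param sigma_fraction Gaussian sigma as a fraction of K, in `(0, 1]`.
#' @return the apodized `subspeckle_stack`.
#' @export
apodize <- function(stack, sigma_fraction = 0.125) {
  if (!(sigma_fraction > 0 && sigma_fraction <= 1)) {
    stop("sigma_fraction must be in (0, 1]")
  }
  K <- stack$K
  sig <- sigma_fraction * K
  cen <- K %/% 2 + 1
  d2 <- outer((seq_len(K) - cen)^2, (seq_len(K) - cen)^2, "+")
  g <- exp(-d2 / (2 * sig^2))
  n <- dim(stack$tiles)[3]
  out <- stack$tiles
  energy <- numeric(n)
  for (k in seq_len(n)) {
    t <- (out[, , k] - mean(out[, , k])) * g
    energy[k] <- sum(t^2)
    out[, , k] <- t - mean(t)
  }
  keep <- energy >= 1e-6 * stats::median(energy)
  if (!all(keep)) {
    warning(sum(!keep), " degenerate tile(s) dropped (windowed energy < 1e-6 of median)")
    out <- out[, , keep, drop = FALSE]
    stack$origins <- stack$origins[keep, , drop = FALSE]
  }
  stack$tiles <- out
  stack$apodized <- TRUE
  stack$sigma_fraction <- sigma_fraction
  stack
}

# Sparse pixel-driven Radon operator for one angle: each pixel's mass is
# split linearly between the two nearest rho bins, so every projection
# conserves the tile mass exactly.
radon_matrix <- function(K, M, theta_deg) {
  cen <- K %/% 2 + 1
  cb <- M %/% 2 + 1
  x <- rep(seq_len(K) - cen, each = K)     # column offset (matrix is col-major)
  y <- rep(seq_len(K) - cen, times = K)    # row offset
  th <- theta_deg * pi / 180
  pos <- x * cos(th) + y * sin(th) + cb
  i0 <- floor(pos)
  fr <- pos - i0
  j <- rep(seq_len(K * K), 2L)
  i <- c(i0, i0 + 1)
  w <- c(1 - fr, fr)
  i <- pmin(M, pmax(1, i))  # clamp stray corner mass into edge bins
  Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(M, K * K))
}

#' Radon-project sub-speckle tiles onto 1D signals at equally spaced angles
#'
#' For each tile and each angle `theta_a = a * 180 / n_angles`
#' (`a = 0..n_angles-1`), the line-integral projection is accumulated into
#' `M` samples. The default `M` is the next power of two at or above
#' `K * sqrt(2)` so all angles share one bispectrum geometry.
#'
#' @param stack an (ideally apodized) [crop_subspeckles()] result.
#' @param n_angles number of projection angles in `[0, 180)`; default 18.
#' @param M samples per projection, `>= K`; default next power of two
#'   `>= K * sqrt(2)`.
#' @return a `sinogram`: `projections` array `(M, n_angles, N)`, `angles`
#'   (degrees), `K`, `M`, `origins`.
#' @export
radon_project <- function(stack, n_angles = 18L, M = NULL) {
  K <- stack$K
  if (is.null(M)) M <- 2^ceiling(log2(K * sqrt(2)))
  M <- as.integer(M)
  if (n_angles < 1) stop("need at least one angle")
  if (M < K) stop("M must be >= K")
  angles <- (seq_len(n_angles) - 1) * 180 / n_angles
  n <- dim(stack$tiles)[3]
  flat <- matrix(stack$tiles, K * K, n)
  proj <- array(0, c(M, n_angles, n))
  for (a in seq_along(angles)) {
    proj[, a, ] <- as.matrix(radon_matrix(K, M, angles[a]) %*% flat)
  }
  structure(list(projections = proj, angles = angles, K = K, M = M,
                 origins = stack$origins),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> %d tiles x %d angles x %d samples (K = %d)\n",
              dim(x$projections)[3], length(x$angles), x$M, x$K))
  invisible(x)
}

#' @export
print.subspeckle_stack <- function(x, ...) {
  cat(sprintf("<subspeckle_stack> %d tiles of %d x %d%s\n",
              dim(x$tiles)[3], x$K, x$K,
              if (x$apodized) sprintf(", apodized (sigma = %.2f K)", x$sigma_fraction) else ""))
  invisible(x)
}
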