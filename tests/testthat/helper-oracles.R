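# Brute-force oracles kept deliberately independent of the package's FFT
# implementations: plain shift-multiply sums and index-by-index loops.

# Circular autocorrelation of the mean-subtracted image by direct
# shift-and-multiply sums (one explicit circular shift per lag; no FFT).
direct_autocorrelation <- function(x) {
  x0 <- x - mean(x)
  n <- nrow(x0); m <- ncol(x0)
  ac <- matrix(0, n, m)
  for (di in 0:(n - 1)) for (dj in 0:(m - 1)) {
    shifted <- x0[(((1:n) - 1 + di) %% n) + 1, (((1:m) - 1 + dj) %% m) + 1]
    ac[di + 1, dj + 1] <- sum(x0 * shifted)
  }
  ac  # zero lag at [1, 1]
}

# Circular convolution by quadruple loop.
direct_convolution <- function(o, s) {
  n <- nrow(o); m <- ncol(o)
  out <- matrix(0, n, m)
  for (i in 1:n) for (j in 1:m) {
    acc <- 0
    for (p in 1:n) for (q in 1:m) {
      acc <- acc + o[p, q] * s[(i - p) %% n + 1, (j - q) %% m + 1]
    }
    out[i, j] <- acc
  }
  out
}

# Bispectrum by triple-nested evaluation of the defining sum,
# B(f1,f2) = X(f1) X(f2) X*(f1+f2) with X computed as an explicit DFT sum.
direct_bispectrum <- function(x, f_max) {
  M <- length(x)
  X <- vapply(0:(M - 1), function(f) {
    sum(x * exp(-2i * pi * f * (0:(M - 1)) / M))
  }, complex(1))
  B <- matrix(0i, f_max + 1, f_max + 1)
  for (f1 in 0:f_max) for (f2 in 0:f_max) {
    B[f1 + 1, f2 + 1] <- X[f1 + 1] * X[f2 + 1] * Conj(X[(f1 + f2) %% M + 1])
  }
  B
}

# 2D DTFT of an image (center-origin convention matching ft2c on odd grids),
# evaluated at arbitrary frequency coordinates (kx, ky) in index units.
dtft2 <- function(img, kx, ky) {
  W <- nrow(img)
  cen <- W %/% 2 + 1
  x <- col(img) - cen
  y <- row(img) - cen
  sum(img * exp(-2i * pi * (kx * x + ky * y) / W))
}

# 2D DTFT with an arbitrary frequency period M (the projection FT grid):
# offsets are taken about the tile's centered origin.
dtft2_on_m <- function(tile, kx, ky, M) {
  cen <- nrow(tile) %/% 2 + 1
  x <- col(tile) - cen
  y <- row(tile) - cen
  sum(tile * exp(-2i * pi * (kx * x + ky * y) / M))
}

# Phasor distance |e^{i a} - e^{i b}|.
phasor_dist <- function(a, b) Mod(exp(1i * a) - exp(1i * b))

# Small deterministic test image with strict positivity and asymmetry.
toy_image <- function(W = 33, seed = 7) {
  set.seed(seed)
  img <- matrix(0, W, W)
  img[10:24, 12:20] <- matrix(runif(15 * 9), 15, 9)
  img[12:14, 14] <- 3
  img[20:22, 18] <- 2
  img
}

fast_sim <- function(seed = 1, support = 32) {
  simulate_speckle(preset_config("fast", seed = seed), support = support)
}
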