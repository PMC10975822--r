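# Fienup-type iterative phase retrieval (HIO then ER) from the recovered
# Fourier amplitude: the baseline the bispectrum route replaces. Random
# initial phases make its output ambiguous up to translation and 180-degree
# rotation, and different seeds can land in different equivalence classes.

#' Configuration for the Fienup ER/HIO baseline
#'
#' @param beta HIO feedback parameter in `(0, 1]`.
#' @param n_hio number of HIO iterations per restart.
#' @param n_er number of ER iterations per restart (after HIO).
#' @param n_restarts random restarts; the best Fourier residual wins.
#' @param support binary support mask (same grid as the amplitude) or `NULL`
#'   for a centered box of half the grid side.
#' @param seed integer seed for the random initial phases.
#' @return a `fienup_config` list.
#' @export
fienup_config <- function(beta = 0.9, n_hio = 200L, n_er = 50L,
                          n_restarts = 1L, support = NULL, seed = 1L) {
  if (!(beta > 0 && beta <= 1)) stop("beta must be in (0, 1]")
  if (n_hio < 1 || n_er < 1) stop("iteration counts must be >= 1")
  structure(list(beta = beta, n_hio = as.integer(n_hio),
                 n_er = as.integer(n_er), n_restarts = as.integer(n_restarts),
                 support = support, seed = as.integer(seed)),
            class = "fienup_config")
}

fourier_residual <- function(g, amp) {
  G <- ft2c(g)
  sqrt(sum((Mod(G) - amp)^2)) / sqrt(sum(amp^2))
}

#' Iterative ER/HIO phase retrieval from a Fourier amplitude
#'
#' Alternates Fourier-magnitude projection with object-domain constraints
#' (support and nonnegativity): `n_hio` HIO iterations (feedback `beta`
#' outside the constraint set) followed by `n_er` ER iterations, over
#' `n_restarts` random initializations; the restart with the smallest
#' relative Fourier residual `||FT(g)| - A|| / ||A||` is returned.
#'
#' @param amplitude a [fourier_amplitude()] result or nonnegative matrix
#'   (DC centered).
#' @param config a [fienup_config()].
#' @param init_phase optional initial Fourier phase matrix (overrides the
#'   random start; `n_restarts` is then ignored).
#' @return list with `image` (nonnegative, peak-normalized), `residual`
#'   (best final residual), `trace` (per-iteration residuals of the best
#'   restart, HIO then ER), `er_trace` (ER portion), `restart` (index won).
#' @export
fienup_retrieve <- function(amplitude, config = fienup_config(),
                            init_phase = NULL) {
  amp <- if (inherits(amplitude, "fourier_amplitude")) amplitude$magnitudes else amplitude
  n <- nrow(amp)
  sup <- config$support
  if (is.null(sup)) {
    h <- n %/% 4
    cen <- n %/% 2 + 1
    sup <- matrix(FALSE, n, n)
    sup[(cen - h):(cen + h), (cen - h):(cen + h)] <- TRUE
  }
  sup <- sup > 0

  run_once <- function(phi0) {
    g <- Re(ift2c(amp * exp(1i * phi0)))
    trace <- numeric(config$n_hio + config$n_er)
    for (it in seq_len(config$n_hio)) {
      G <- ft2c(g)
      trace[it] <- sqrt(sum((Mod(G) - amp)^2)) / sqrt(sum(amp^2))
      Gp <- amp * exp(1i * Arg(G))
      gp <- Re(ift2c(Gp))
      viol <- !sup | gp < 0
      g <- ifelse(viol, g - config$beta * gp, gp)
    }
    for (it in seq_len(config$n_er)) {
      G <- ft2c(g)
      trace[config$n_hio + it] <- sqrt(sum((Mod(G) - amp)^2)) / sqrt(sum(amp^2))
      Gp <- amp * exp(1i * Arg(G))
      gp <- Re(ift2c(Gp))
      gp[!sup | gp < 0] <- 0
      g <- gp
    }
    list(g = g, res = fourier_residual(g, amp), trace = trace)
  }

  runs <- if (!is.null(init_phase)) {
    list(run_once(init_phase))
  } else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(config$seed)
    lapply(seq_len(config$n_restarts), function(k) {
      run_once(matrix(stats::runif(n * n, -pi, pi), n, n))
    })
  }
  best <- which.min(vapply(runs, function(r) r$res, numeric(1)))
  g <- runs[[best]]$g
  g[g < 0] <- 0
  if (max(g) > 0) g <- g / max(g)
  trace <- runs[[best]]$trace
  list(image = g, residual = runs[[best]]$res, trace = trace,
       er_trace = trace[(config$n_hio + 1):length(trace)], restart = best)
}
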