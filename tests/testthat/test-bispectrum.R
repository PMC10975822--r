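test_that("truncation schemes retain the low-frequency index box", {
  sch <- truncation_scheme(0.7, 300)
  expect_equal(sch$f_max, 90)
  expect_equal((sch$f_max + 1)^2, 8281)
  expect_equal(retained_fraction(sch), 8281 / 90000)
  expect_gt(1 - retained_fraction(sch), 0.80)

  expect_equal(retained_fraction(truncation_scheme(0, 64)), 1)

  fr <- vapply(seq(0, 0.9, 0.1),
               function(C) retained_fraction(truncation_scheme(C, 300)),
               numeric(1))
  expect_true(all(diff(fr) < 0))

  expect_error(truncation_scheme(1, 300), "must be in")
  expect_error(truncation_scheme(-0.1, 300), "must be in")
})

test_that("the full 4D bispectrum element count is P^4", {
  expect_identical(full_bispectrum_count(256), 4294967296)
  expect_equal(signif(full_bispectrum_count(256), 1), 4e9)
  expect_identical(full_bispectrum_count(1), 1)
  expect_identical(full_bispectrum_count(10), 10000)
  expect_error(full_bispectrum_count(0), ">= 1")
})

test_that("the truncated bispectrum matches the defining triple product", {
  # constant signal: only the DC element survives
  sch <- truncation_scheme(0, 8)
  B <- truncated_bispectrum(rep(2, 8), sch)
  expect_equal(Mod(B[1, 1]), 16^3, tolerance = 1e-9)
  expect_lt(max(Mod(B[-1, ])), 1e-9)
  expect_lt(max(Mod(B[, -1])), 1e-9)

  # index-by-index brute-force oracle, full and truncated, with wrap
  for (seed in 1:4) {
    set.seed(seed)
    M <- sample(6:16, 1)
    x <- runif(M)
    sch <- truncation_scheme(0, M)
    expect_equal(truncated_bispectrum(x, sch),
                 direct_bispectrum(x, sch$f_max), tolerance = 1e-12)
    schT <- truncation_scheme(0.5, M)
    expect_equal(truncated_bispectrum(x, schT),
                 direct_bispectrum(x, schT$f_max), tolerance = 1e-12)
  }

  # symmetry B(f1,f2) = B(f2,f1)
  set.seed(9)
  x <- runif(16)
  B <- truncated_bispectrum(x, truncation_scheme(0.3, 16))
  expect_equal(B, t(B), tolerance = 1e-12)

  expect_error(truncated_bispectrum(c(1, NA, 3, 4), truncation_scheme(0, 4)),
               "finite")
  expect_error(truncated_bispectrum(runif(8), truncation_scheme(0, 16)),
               "length")
})

test_that("bispectrum averaging is the complex ensemble mean", {
  sch <- truncation_scheme(0.5, 16)
  set.seed(2)
  x <- runif(16)
  B <- truncated_bispectrum(x, sch)

  # idempotence on identical tiles
  avg <- average_bispectra(list(B, B, B), sch)
  expect_equal(avg$values[, , 1], B, tolerance = 1e-12)
  expect_equal(avg$n_averaged, 3)

  # mean of conjugate-paired inputs is real
  avg2 <- average_bispectra(list(B, Conj(B)), sch)
  expect_lt(max(abs(Im(avg2$values))), 1e-12)

  expect_error(average_bispectra(list(B, B[1:3, 1:3]), sch), "mismatched")
  expect_error(average_bispectra(list(), sch), "at least one")
})

test_that("averaged bispectrum phase noise shrinks like 1/sqrt(N)", {
  sch <- truncation_scheme(0.5, 32)
  set.seed(42)
  base <- pmax(0.2, stats::dnorm(1:32, 12, 4) * 20 + stats::dnorm(1:32, 20, 3) * 10)
  Ns <- c(2, 8, 32)
  sds <- vapply(Ns, function(N) {
    phases <- vapply(1:100, function(rep) {
      tiles <- lapply(1:N, function(k) {
        truncated_bispectrum(base + stats::rnorm(32, sd = 0.5), sch)
      })
      Arg(average_bispectra(tiles, sch)$values[2, 3, 1])
    }, numeric(1))
    # circular standard deviation about the mean phasor direction
    z <- mean(exp(1i * phases))
    stats::sd(Arg(exp(1i * phases) * Conj(z)))
  }, numeric(1))
  expect_lt(stats::cor(log(Ns), log(sds)), -0.8)
})

test_that("recursive phase closure recovers the gauge-fixed true phase", {
  M <- 32
  # shifted delta: purely linear true phase, recovered phase identically 0
  x <- numeric(M); x[8] <- 1
  avg <- average_bispectra(list(truncated_bispectrum(x, truncation_scheme(0, M))),
                           truncation_scheme(0, M))
  rp <- recover_phase_recursive(avg, 1)
  expect_lt(max(abs(rp$phase)), 1e-9)
  expect_equal(rp$f_reachable, 16)

  for (seed in 1:3) {
    set.seed(seed)
    x <- runif(M)
    tru <- Arg(stats::fft(x))
    for (C in c(0, 0.5)) {
      sch <- truncation_scheme(C, M)
      avg <- average_bispectra(list(truncated_bispectrum(x, sch)), sch)
      for (w in c("modulus", "none")) {
        ph <- recover_phase_recursive(avg, 1, weights = w)$phase
        f <- 0:(length(ph) - 1)
        gauge <- tru[f + 1] - f * tru[2]
        expect_lt(max(phasor_dist(ph, gauge)), 1e-6)
      }
    }
  }
})

test_that("phase recovery is gauge- and translation-invariant", {
  M <- 32
  set.seed(5)
  x <- runif(M)
  sch <- truncation_scheme(0.4, M)
  rec <- function(sig) {
    avg <- average_bispectra(list(truncated_bispectrum(sig, sch)), sch)
    recover_phase_recursive(avg, 1)$phase
  }
  base <- rec(x)
  # positive scaling leaves the phase unchanged
  expect_equal(rec(7.3 * x), base, tolerance = 1e-9)
  # circular shift changes the true phase by a ramp only; the gauge-fixed
  # recovered phase is unchanged
  expect_lt(max(phasor_dist(rec(x[c(6:M, 1:5)]), base)), 1e-6)
})

test_that("speckle bispectrum phase concentrates on reality as tiles accrue", {
  # point object: tiles are PSF-only, and the bispectrum transfer function is
  # real in expectation, so the averaged phase should cluster near zero and
  # tighten with the ensemble size
  cfg <- preset_config("fast", seed = 3)
  psf <- make_incoherent_psf(make_phase_screen(c(512, 512), seed = 3), cfg)
  sch <- NULL
  mean_cos <- function(stride) {
    st <- apodize(crop_subspeckles(psf$intensities, 128, stride), 0.125)
    sino <- radon_project(st, 6)
    sch <<- truncation_scheme(0.85, sino$M)
    avg <- speckle_bispectrum(sino, sch)
    mean(cos(Arg(avg$values[2:7, 2:7, ])))
  }
  few <- mean_cos(128)   # N = 16
  many <- mean_cos(32)   # N = 169
  expect_gt(many, 0.5)
  expect_gt(many, few - 0.05)
})
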