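test_that("glyph objects rasterize deterministically with correct support", {
  dot <- make_object("dot", c(256, 256), 1)
  expect_equal(sum(dot$intensities > 0), 1)
  expect_equal(dot$intensities[129, 129], 1)

  obj <- make_object("5", c(2048, 2048), 42)
  nz <- which(obj$intensities > 0, arr.ind = TRUE)
  expect_lte(max(nz[, 1]) - min(nz[, 1]) + 1, 42)
  expect_gte(max(nz[, 1]) - min(nz[, 1]) + 1, 40)

  expect_error(make_object("q", c(128, 128), 8), "unknown glyph")
  expect_error(make_object("5", c(64, 64), 40), "canvas/4")

  # pixel-count oracle: count target pixels mapped to each mask cell
  for (g in setdiff(glyph_ids(), "dot")) {
    mask <- bispeckle:::.glyph_masks[[g]]
    h <- nrow(mask); w <- ncol(mask)
    h2 <- 21L
    w2 <- max(1L, as.integer(round(h2 * w / h)))
    cnt <- 0L
    for (i in seq_len(h)) for (j in seq_len(w)) {
      if (mask[i, j] == 1) {
        ni <- sum(pmin(h, pmax(1, ceiling(seq_len(h2) * h / h2))) == i)
        nj <- sum(pmin(w, pmax(1, ceiling(seq_len(w2) * w / w2))) == j)
        cnt <- cnt + ni * nj
      }
    }
    obj <- make_object(g, c(128, 128), 21)
    expect_equal(sum(obj$intensities > 0), cnt, info = g)
  }
})

test_that("phase screens are seeded, uniform and in range", {
  s1 <- make_phase_screen(c(64, 64), seed = 0)
  s2 <- make_phase_screen(c(64, 64), seed = 0)
  expect_identical(s1$phases, s2$phases)
  expect_true(all(s1$phases >= 0 & s1$phases < 2 * pi))

  s <- make_phase_screen(c(512, 512), seed = 3)
  ks <- suppressWarnings(stats::ks.test(as.vector(s$phases), "punif", 0, 2 * pi))
  # 1% critical value of the KS statistic for large n
  expect_lt(unname(ks$statistic), 1.628 / sqrt(length(s$phases)))
  expect_error(make_phase_screen(c(0, 64)), "positive")
})

test_that("the incoherent PSF is normalized and speckle-like", {
  cfg <- preset_config("fast", seed = 2)

  flat <- structure(list(phases = matrix(0, 512, 512)), class = "phase_screen")
  p0 <- make_incoherent_psf(flat, cfg)
  expect_equal(sum(p0$intensities), 1, tolerance = 1e-12)
  # no scattering: aperture diffraction, energy concentrated in central lobe
  lobe <- bispeckle:::center_crop(p0$intensities, 31)
  expect_gt(sum(lobe), 0.5)

  scr <- make_phase_screen(c(512, 512), seed = 2)
  psf <- make_incoherent_psf(scr, cfg)
  expect_equal(sum(psf$intensities), 1, tolerance = 1e-12)
  expect_true(all(psf$intensities >= 0))

  # speckle-like: sharply peaked autocorrelation, against the direct oracle
  # (peak against the mean magnitude of the off-peak lags, 64^2 crop)
  crop <- psf$intensities[1:64, 1:64]
  ac <- direct_autocorrelation(crop)
  expect_gt(ac[1, 1] / mean(abs(ac[-1])), 10)

  big <- scene_config(sensor_shape = c(64, 64), aperture_diameter = 2.5e-3)
  expect_error(make_incoherent_psf(make_phase_screen(c(64, 64)), big),
               "aperture larger")
})

test_that("speckle rendering is an exact circular convolution", {
  cfg <- scene_config(sensor_shape = c(64, 64), aperture_diameter = 1e-4,
                      seed = 5)
  scr <- make_phase_screen(c(64, 64), seed = 5)
  psf <- make_incoherent_psf(scr, cfg)

  # delta object reproduces the (circularly shifted) PSF exactly
  delta <- matrix(0, 64, 64); delta[33, 33] <- 1
  fr <- render_speckle(delta, psf)
  expect_equal(fr$intensities, bispeckle:::circshift2(psf$intensities, 32, 32),
               tolerance = 1e-12)

  # energy conservation
  obj <- make_object("4", c(64, 64), 12)
  fr <- render_speckle(obj, psf)
  expect_equal(sum(fr$intensities),
               sum(obj$intensities) * sum(psf$intensities),
               tolerance = 1e-9)

  # FFT route vs quadruple-loop direct circular convolution
  set.seed(11)
  o <- matrix(runif(16 * 16), 16, 16)
  s <- matrix(runif(16 * 16), 16, 16)
  expect_equal(render_speckle(o, s)$intensities, direct_convolution(o, s),
               tolerance = 1e-9)

  expect_error(render_speckle(matrix(1, 8, 8), matrix(1, 9, 9)), "must match")

  # shot noise is seeded and deterministic
  n1 <- render_speckle(obj, psf, photon_budget = 1e5, seed = 9)
  n2 <- render_speckle(obj, psf, photon_budget = 1e5, seed = 9)
  expect_identical(n1$intensities, n2$intensities)
})

test_that("memory-effect shift invariance holds exactly", {
  cfg <- scene_config(sensor_shape = c(64, 64), aperture_diameter = 1e-4,
                      seed = 8)
  psf <- make_incoherent_psf(make_phase_screen(c(64, 64), seed = 8), cfg)
  obj <- make_object("bars", c(64, 64), 10)$intensities
  base <- render_speckle(obj, psf)$intensities
  shifted <- render_speckle(bispeckle:::circshift2(obj, 5, -3), psf)$intensities
  expect_equal(shifted, bispeckle:::circshift2(base, 5, -3), tolerance = 1e-12)
})

test_that("point-object speckle has fully developed contrast", {
  cfg <- preset_config("fast", seed = 4)
  psf <- make_incoherent_psf(make_phase_screen(c(512, 512), seed = 4), cfg)
  fr <- psf$intensities
  expect_gt(stats::sd(fr) / mean(fr), 0.5)
})

test_that("field-of-view and resolution calculators match closed forms", {
  cfg <- scene_config(wavelength = 530e-9, object_distance = 0.64,
                      diffuser_thickness = 1e-3,
                      diffuser_camera_distance = 0.085,
                      aperture_diameter = 2.5e-3)
  expect_equal(fov_limit(cfg), 0.64 * 530e-9 / (pi * 1e-3), tolerance = 1e-12)
  expect_equal(fov_limit(cfg), 1.0798e-4, tolerance = 1e-4)
  expect_equal(diffraction_limit(cfg), 1.22 * 530e-9 * 0.085 / 2.5e-3,
               tolerance = 1e-12)

  # scaling laws
  cfg2 <- cfg; cfg2$diffuser_thickness <- 2e-3
  expect_equal(fov_limit(cfg2), fov_limit(cfg) / 2)
  cfg3 <- cfg; cfg3$diffuser_camera_distance <- 0.17
  expect_equal(diffraction_limit(cfg3), 2 * diffraction_limit(cfg))

  expect_error(scene_config(diffuser_thickness = -1), "positive")
  expect_error(scene_config(sensor_shape = c(32, 128)), ">= 64")
})
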