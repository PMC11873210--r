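test_that("ITD jnd transform is odd, increasing and calibrated near zero", {
  expect_identical(itd_to_jnd(0), 0)
  expect_equal(itd_to_jnd(20), 1.0)
  x <- c(5, 50, 200, 600, 900, 1500)
  expect_equal(itd_to_jnd(-x), -itd_to_jnd(x))
  expect_true(all(diff(itd_to_jnd(seq(-1200, 1200, by = 10))) > 0))
  # a tabulated curve can be substituted
  crv <- cbind(c(0, 10, 100), c(0, 1, 2))
  expect_equal(itd_to_jnd(10, crv), 1)
  expect_equal(itd_to_jnd(55, crv), 1.5)
})

test_that("synthetic HRTFs have spherical-head ITD and mirror symmetry", {
  g <- direction_grid(interaural_polar_inverse(
    c(0, 0, 30, -30, 60), c(0, 120, 45, 45, 200)))
  h <- synth_hrtf(g, fb30, params_symmetric, seed = 1)
  expect_equal(h$itd_us[1:2], c(0, 0))                 # midsagittal plane
  # mirrored pair: spectra exchanged, ITD negated
  expect_equal(h$itd_us[3], -h$itd_us[4])
  expect_equal(h$logmag_left[3, ], h$logmag_right[4, ])
  expect_equal(h$logmag_right[3, ], h$logmag_left[4, ])
  # Woodworth magnitude at 60 degrees lateral
  latr <- 60 * pi / 180
  expect_equal(h$itd_us[5], 1e6 * 0.0875 / 343 * (latr + sin(latr)))
  expect_error(synth_hrtf_params(head_radius_m = 0), "head radius")
})

test_that("synthetic templates are pairwise distinct over a dense grid", {
  g <- uniform_sphere_grid(200)
  h <- synth_hrtf(g, fb30, seed = 7)
  feat <- cbind(h$logmag_left, h$logmag_right, h$itd_us)
  d <- as.matrix(dist(feat))
  diag(d) <- Inf
  expect_gt(min(d), 0.05)
  # determinism
  h2 <- synth_hrtf(g, fb30, seed = 7)
  expect_identical(h2$logmag_left, h$logmag_left)
})

test_that("spherical-harmonics resampling interpolates and recovers harmonics", {
  g <- uniform_sphere_grid(100)
  h <- synth_hrtf(g, fb30, seed = 3)
  # square system: exact interpolation identity
  r <- sh_resample(h, g, order = 9, tikhonov_lambda = 0)
  expect_equal(r$logmag_left, h$logmag_left, tolerance = 1e-6)
  expect_equal(r$itd_us, h$itd_us, tolerance = 1e-6)
  # constant field stays constant on a new grid
  hc <- hrtf_set(g, matrix(3, 100, 30), matrix(3, 100, 30), rep(0, 100), fb30)
  rc <- sh_resample(hc, uniform_sphere_grid(50), order = 4,
                    tikhonov_lambda = 1e-8)
  expect_equal(unname(rc$logmag_left), matrix(3, 50, 30), tolerance = 1e-5)
  # an exact degree-3 harmonic field is recovered exactly
  g2 <- uniform_sphere_grid(200)
  y <- real_sh_basis(g2, 3)[, 14]
  hy <- hrtf_set(g2, matrix(y, 200, 30), matrix(y, 200, 30), y, fb30)
  ry <- sh_resample(hy, g2, order = 3, tikhonov_lambda = 0)
  expect_equal(ry$logmag_left[, 1], y, tolerance = 1e-6)
  # linearity of the resampling operator
  ha <- synth_hrtf(g, fb30, seed = 4)
  hsum <- hrtf_set(g, h$logmag_left + ha$logmag_left,
                   h$logmag_right + ha$logmag_right,
                   h$itd_us + ha$itd_us, fb30)
  tgt <- uniform_sphere_grid(60)
  r1 <- sh_resample(h, tgt, 6, 1e-6)
  r2 <- sh_resample(ha, tgt, 6, 1e-6)
  rs <- sh_resample(hsum, tgt, 6, 1e-6)
  expect_equal(rs$logmag_left, r1$logmag_left + r2$logmag_left,
               tolerance = 1e-9)
  expect_error(sh_resample(h, g, order = 15), "at least")
})

test_that("rank-deficient SH fits advise regularization", {
  # all directions on one circle: zonal structure makes the fit singular
  ang <- seq(0, 2 * pi, length.out = 38)[1:36]
  g <- direction_grid(cbind(cos(ang), sin(ang), 0))
  h <- hrtf_set(g, matrix(1, 36, 30), matrix(1, 36, 30), rep(0, 36), fb30)
  expect_error(sh_resample(h, g, order = 5, tikhonov_lambda = 0),
               "tikhonov_lambda")
  expect_silent(r <- sh_resample(h, g, order = 5, tikhonov_lambda = 1e-6))
})

test_that("SOFA files round-trip the generating HRTF set", {
  g <- uniform_sphere_grid(16)
  h <- synth_hrtf(g, fb30, seed = 2)
  f <- withr::local_tempfile(fileext = ".sofa")
  write_sofa(h, f, phase = "linear")
  h2 <- load_sofa(f, fb30, itd_method = "xcorr")
  expect_lt(max(abs(h2$logmag_left - h$logmag_left)), 0.1)
  expect_lt(max(abs(h2$logmag_right - h$logmag_right)), 0.1)
  expect_lt(max(abs(h2$itd_us - h$itd_us)), 2)
  expect_lt(max(abs(h2$grid$unit_vectors - h$grid$unit_vectors)), 1e-9)
  # minimum-phase responses: onset-based ITD within the band-limited rise
  write_sofa(h, f, phase = "minimum")
  h3 <- load_sofa(f, fb30, itd_method = "onset")
  expect_lt(max(abs(h3$logmag_left - h$logmag_left)), 0.1)
  expect_lt(max(abs(h3$itd_us - h$itd_us)), 60)
})

test_that("single-position and ear-swapped SOFA fixtures load correctly", {
  g1 <- direction_grid(interaural_polar_inverse(25, 40))
  h1 <- synth_hrtf(g1, fb30, seed = 5)
  f <- withr::local_tempfile(fileext = ".sofa")
  write_sofa(h1, f, phase = "linear")
  r1 <- load_sofa(f, fb30, itd_method = "xcorr")
  expect_identical(r1$grid$n, 1L)
  # swapping the ears negates the ITD and exchanges the spectra
  hsw <- hrtf_set(g1, h1$logmag_right, h1$logmag_left, -h1$itd_us, fb30)
  fsw <- withr::local_tempfile(fileext = ".sofa")
  write_sofa(hsw, fsw, phase = "linear")
  rsw <- load_sofa(fsw, fb30, itd_method = "xcorr")
  expect_equal(rsw$itd_us, -r1$itd_us, tolerance = 1e-6)
  expect_equal(rsw$logmag_left, r1$logmag_right, tolerance = 1e-6)
})

test_that("malformed SOFA input fails with the offending field named", {
  bad <- withr::local_tempfile(fileext = ".sofa")
  res <- system2(Sys.which("python"),
                 c("-c", shQuote(sprintf(
                   "import h5py; h5py.File(%s, 'w').close()", dQuote(bad, '"')))))
  expect_identical(res, 0L)
  expect_error(load_sofa(bad, fb30), "SOFAConventions")
})
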