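test_that("ERB-number scale is the Glasberg-Moore map and inverts cleanly", {
  expect_identical(erb_number(0), 0)
  # direct evaluation of 21.4 * log10(0.00437 f + 1) at 1 kHz
  expect_equal(erb_number(1000), 21.4 * log10(0.00437 * 1000 + 1))
  expect_equal(erb_number(1000), 15.62145, tolerance = 1e-6)
  expect_gt(erb_number(12000), erb_number(300))
  f <- exp(seq(log(20), log(20000), length.out = 200))
  expect_true(all(diff(erb_number(f)) > 0))
  expect_equal(erb_to_hz(erb_number(f)), f, tolerance = 1e-6)
  expect_error(erb_number(-1), "0")
})

test_that("filterbank spans the band with ERB-uniform spacing", {
  expect_identical(fb30$n_channels, 30L)
  expect_equal(fb30$centre_frequencies_hz[1], 300)
  expect_lte(fb30$centre_frequencies_hz[30], 12000)
  e <- erb_number(fb30$centre_frequencies_hz)
  expect_equal(diff(e), rep(1, 29), tolerance = 1e-9)
  expect_identical(make_filterbank(300, 12000, 0.5)$n_channels, 59L)
  expect_identical(make_filterbank(300, 300 + 1e-6, 1)$n_channels, 1L)
  expect_error(make_filterbank(300, 200, 1), "f_lo")
  expect_error(make_filterbank(300, 12000, 0), "spacing")
})

test_that("filterbank serializes to JSON and back", {
  path <- withr::local_tempfile(fileext = ".json")
  write_filterbank_json(fb30, path)
  fb2 <- read_filterbank_json(path)
  expect_equal(fb2$centre_frequencies_hz, fb30$centre_frequencies_hz)
  expect_identical(fb2$n_channels, 30L)
})

test_that("frame log-magnitudes scale with gain and clamp silence", {
  fs <- 44100
  x <- tone(fb30$centre_frequencies_hz[15], fs)
  a <- frame_logmag(x, fs, fb30)
  b <- frame_logmag(2 * x, fs, fb30)
  expect_equal(b[15] - a[15], 20 * log10(2), tolerance = 0.01)
  # adding k dB of broadband gain adds k dB to every channel
  k <- 7.3
  withr::with_seed(1, {
    w <- rnorm(8820, sd = 0.05)
    g1 <- frame_logmag(w, fs, fb30)
    g2 <- frame_logmag(w * 10^(k / 20), fs, fb30)
    expect_equal(g2 - g1, rep(k, 30), tolerance = 0.1)
  })
  silent <- frame_logmag(rep(0, 1000), fs, fb30)
  expect_true(all(silent == -120))
})

test_that("white-noise frames are flat after per-channel bandwidth correction", {
  fs <- 44100
  withr::with_seed(2, {
    acc <- matrix(0, 80, 30)
    for (r in 1:80)
      acc[r, ] <- frame_logmag(rnorm(8820, sd = 0.05), fs, fb30)
  })
  bw <- fb30$band_hi_hz - fb30$band_lo_hz
  flat <- colMeans(acc) - 10 * log10(bw)
  expect_lt(max(flat) - min(flat), 1.0)     # dB spread across channels
})

test_that("corpus chopping yields exact frame counts and skips junk", {
  fs <- 8000
  d <- withr::local_tempdir()
  withr::with_seed(3, {
    write_wav(rnorm(5.0 * fs, sd = 0.1), fs, file.path(d, "a.wav"))
    write_wav(rnorm(0.1 * fs, sd = 0.1), fs, file.path(d, "b.wav"))
    write_wav(rnorm(1.05 * fs, sd = 0.1), fs, file.path(d, "c.wav"))
  })
  writeLines("not audio", file.path(d, "broken.wav"))
  files <- file.path(d, c("a.wav", "b.wav", "c.wav"))
  expect_length(chop_corpus(files[1]), 25)
  expect_length(chop_corpus(files[2]), 0)
  expect_length(chop_corpus(files[3]), 5)
  expect_warning(res <- chop_corpus(file.path(d, c("broken.wav", "a.wav"))),
                 "broken.wav")
  expect_length(res, 25)
  # fully silent frames are dropped (first 0.4 s -> 2 of 5 frames)
  quiet <- withr::with_seed(6, c(rep(0, 3200), rnorm(4800, sd = 0.1)))
  write_wav(quiet, fs, file.path(d, "q.wav"))
  expect_length(chop_corpus(file.path(d, "q.wav")), 3)
})

test_that("WAV files round-trip through the reader in PCM and float", {
  fs <- 8000
  x <- withr::with_seed(4, rnorm(4000, sd = 0.2))
  p16 <- withr::local_tempfile(fileext = ".wav")
  write_wav(x, fs, p16, bits = 16)
  r16 <- read_wav(p16)
  expect_equal(r16$fs, fs)
  expect_equal(r16$samples, x, tolerance = 1e-4)
  p32 <- withr::local_tempfile(fileext = ".wav")
  write_wav(cbind(x, -x), fs, p32, bits = 32)   # stereo averages to ~0
  r32 <- read_wav(p32)
  expect_identical(r32$n_channels, 2L)
  expect_lt(max(abs(r32$samples)), 1e-6)
})
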