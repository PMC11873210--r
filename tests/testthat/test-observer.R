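test_that("assembled covariances have the right structure per representation", {
  nm <- noise_model(0.9, 1.1)
  # ISD: the source term vanishes exactly
  f_isd <- build_feature_map("ISD", fb30)
  S_noise <- f_isd$A %*% diag(c(0.9, rep(1.1, 60))^2) %*% t(f_isd$A)
  expect_equal(assemble_covariance(nm, prior_known, f_isd), S_noise,
               tolerance = 1e-12)
  # zero source covariance: pure noise term
  f_bin <- build_feature_map("BIN_SG", fb30)
  p0 <- source_prior(rep(0, 30), matrix(0, 30, 30), "LOGMAG")
  S0 <- assemble_covariance(nm, p0, f_bin)
  expect_equal(S0, assemble_covariance(nm, NULL, f_bin), tolerance = 1e-12)
  # full covariance: ILD row/column untouched by the source term
  S <- assemble_covariance(nm, prior_known, f_bin)
  expect_equal(S[2, ], S0[2, ], tolerance = 1e-9)
  # left and right SG blocks get identical source blocks with full
  # cross-ear correlation
  src <- S - S0
  L <- f_bin$left_rows; R <- f_bin$right_rows
  expect_equal(src[L, L], src[R, R], tolerance = 1e-9)
  expect_equal(src[L, R], src[L, L], tolerance = 1e-9)
  expect_error(noise_model(0), "> 0")
})

test_that("BIN_SG covariance matches Monte-Carlo noise + source sampling", {
  nm <- noise_model(1, 1)
  fmap <- build_feature_map("BIN_SG", fb30)
  S <- assemble_covariance(nm, prior_known, fmap)
  n <- 20000
  Zsrc <- draw_prior(prior_known, n, seed = 15)
  Zsrc <- Zsrc - rowMeans(Zsrc)
  raw <- withr::with_seed(16, matrix(rnorm(61 * n), 61)) +
    rbind(0, Zsrc, Zsrc)
  emp <- cov(t(featurize(fmap, raw)))
  expect_lt(max(abs(emp - S)) / max(diag(S)), 0.05)
})

test_that("templates combine HRTF filtering with the prior mean", {
  g <- grid_small
  zero_h <- hrtf_set(g, matrix(0, g$n, 30), matrix(0, g$n, 30),
                     rep(0, g$n), fb30)
  flat_p <- source_prior(rep(20, 30), diag(30), "LOGMAG")
  fmap <- build_feature_map("BIN_SG", fb30)
  Tm <- build_templates(zero_h, flat_p, fmap)
  expect_equal(max(abs(Tm)), 0)                      # flat prior: zero SG/ILD
  # adding a constant to the prior mean leaves SG/ILD/ISD templates alone
  fisd <- build_feature_map("ISD", fb30)
  for (fm in list(fmap, fisd)) {
    t1 <- build_templates(hrtf_small, flat_p, fm)
    p2 <- source_prior(rep(35, 30), diag(30), "LOGMAG")
    expect_equal(build_templates(hrtf_small, p2, fm), t1, tolerance = 1e-10)
  }
  # notch channels vary with polar angle
  Tm2 <- build_templates(hrtf_small, flat_p, fmap)
  sg_spread <- apply(Tm2[fmap$left_rows, ], 1, sd)
  expect_gt(max(sg_spread), 1)
})

test_that("log-likelihood equals the dense Gaussian density", {
  dec <- decoder_model(hrtf_small, prior_known, "BIN_SG")
  x <- dec$templates[, 17] + withr::with_seed(17, rnorm(60, sd = 0.5))
  ll <- log_likelihood(x, dec)
  Sinv <- solve(dec$Sigma)
  ld <- determinant(dec$Sigma)$modulus
  dense <- vapply(seq_len(dec$grid$n), function(j) {
    d <- x - dec$templates[, j]
    -0.5 * drop(t(d) %*% Sinv %*% d) - 0.5 * ld - 30 * log(2 * pi)
  }, 0)
  expect_equal(ll, dense, tolerance = 1e-9, ignore_attr = TRUE)
  # noiseless template maximizes its own likelihood
  expect_identical(which.max(log_likelihood(dec$templates[, 17], dec)), 17L)
})

test_that("scaling the covariance rescales log-likelihood differences", {
  d1 <- decoder_model(hrtf_small, NULL, "ISD", noise_model(1, 1))
  d2 <- decoder_model(hrtf_small, NULL, "ISD", noise_model(2, 2))
  x <- d1$templates[, 5] + withr::with_seed(18, rnorm(31))
  l1 <- log_likelihood(x, d1)
  l2 <- log_likelihood(x, d2)
  expect_equal(l2 - l2[1], (l1 - l1[1]) / 4, tolerance = 1e-9)
})

test_that("posterior normalization is exact, stable and prior-aware", {
  expect_equal(as.numeric(posterior(c(3, 3))), c(0.5, 0.5))
  expect_equal(as.numeric(posterior(log(c(1, 2, 4)))), c(1, 2, 4) / 7)
  ll <- withr::with_seed(19, rnorm(100))
  expect_equal(as.numeric(posterior(ll + 1234)), as.numeric(posterior(ll)))
  for (s in 1:20) {
    p <- posterior(withr::with_seed(s, rnorm(500, sd = 50)))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
  }
  w <- c(1, 0, 1)
  expect_equal(as.numeric(posterior(c(0, 0, 0), w)), c(0.5, 0, 0.5))
  expect_error(posterior(rep(-Inf, 3)), "zero likelihood")
})

test_that("MAP estimation picks the mode with deterministic tie-breaks", {
  expect_identical(map_estimate(c(0, 0, 1, 0)), 3L)
  expect_identical(map_estimate(rep(0.25, 4)), 1L)
  ll <- withr::with_seed(20, rnorm(300))
  expect_identical(map_estimate(posterior(ll)), which.max(ll))
})

test_that("noiseless decoding returns the true direction everywhere", {
  prior <- build_prior(synth_corpus(fb30, 5000, seed = 21), "synthetic")
  for (rep_tag in c("LOGMAG", "ISD", "BIN_SG", "POS_SG", "IPSI_SG")) {
    dec <- decoder_model(hrtf_small, prior, rep_tag)
    tr <- simulate_trials(dec, hrtf_small, prior$mean,
                          seq_len(grid_small$n), noise_draw = FALSE)
    expect_identical(tr$resp_idx, tr$true_idx)
  }
})

test_that("the ISD observer ignores the source spectrum bit-for-bit", {
  dec <- decoder_model(hrtf_small, NULL, "ISD")
  s <- withr::with_seed(22, rnorm(30, sd = 10))
  t1 <- simulate_trials(dec, hrtf_small, rep(0, 30), 1:200, seed = 23)
  t2 <- simulate_trials(dec, hrtf_small, s, 1:200, seed = 23)
  expect_identical(t1$resp_idx, t2$resp_idx)
})

test_that("LOGMAG and gradient features are information-equivalent in the
           large level-variance limit", {
  prior <- build_prior(synth_corpus(fb30, 5000, seed = 24), "synthetic")
  boosted <- source_prior(prior$mean, prior$cov + 1e6, "LOGMAG")
  d_log <- decoder_model(hrtf_small, boosted, "LOGMAG")
  d_bin <- decoder_model(hrtf_small, prior, "BIN_SG")
  dirs <- withr::with_seed(25, sample(grid_small$n, 500, replace = TRUE))
  t_log <- simulate_trials(d_log, hrtf_small, prior$mean, dirs, seed = 26)
  t_bin <- simulate_trials(d_bin, hrtf_small, prior$mean, dirs, seed = 26)
  expect_gte(mean(t_log$resp_idx == t_bin$resp_idx), 0.99)
})

test_that("ipsilateral decoding conditions on the measured ITD sign", {
  prior <- build_prior(synth_corpus(fb30, 5000, seed = 27), "synthetic")
  dec <- decoder_model(hrtf_small, prior, "IPSI_SG")
  left_dir <- which.max(grid_small$lateral_deg)
  x <- dec$templates[, left_dir]
  ll <- log_likelihood(x, dec)
  expect_identical(which.max(ll), left_dir)
  expect_length(ll, grid_small$n)
  # reduced dimension: left sub-model drops the contralateral block
  expect_identical(dec$sub$left$d, 2L + 29L)
})
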