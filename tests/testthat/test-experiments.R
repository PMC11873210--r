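test_that("ripple spectra follow the log-frequency cosine definition", {
  expect_equal(ripple_spectrum(fb30, 0, 2), rep(0, 30))
  r0 <- ripple_spectrum(fb30, 40, 1.5, 0)
  rpi <- ripple_spectrum(fb30, 40, 1.5, pi)
  expect_equal(sg(rpi), -sg(r0), tolerance = 1e-12)   # SG differs only in sign
  expect_equal(max(r0), 20, tolerance = 0.5)          # A/2 envelope
  f <- fb30$centre_frequencies_hz
  expect_equal(r0, 20 * cos(2 * pi * 1.5 * log2(f / 1000)))
  expect_error(ripple_spectrum(fb30, -1, 1), ">= 0")
})

test_that("SG std across ripple density rises to one interior peak then falls", {
  expect_equal(sg_std(rep(3, 10)), 0)
  expect_equal(sg_std(1:10), 0)
  rho <- c(0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8)
  s <- vapply(rho, function(r) sg_std(ripple_spectrum(fb30, 40, r, 0)), 0)
  k <- which.max(s)
  expect_gt(k, 1); expect_lt(k, length(rho))          # interior peak
  expect_true(all(diff(s[1:k]) > 0))
  expect_lt(s[length(rho)], s[k])
  # at 1.5 ripples/octave the source SG exceeds the ecological ~8.5 dB/ERB
  expect_gt(sg_std(ripple_spectrum(fb30, 40, 1.5, 0)), 8.5)
})

test_that("polar error rate counts wrapped errors over threshold", {
  pol <- c(0, 10, 50, 44, 46, 350)
  g <- direction_grid(interaural_polar_inverse(rep(0, 6), pol))
  trials <- data.frame(true_idx = c(rep(1L, 4), 2L), resp_idx = c(2:5, 2L))
  expect_equal(polar_error_rate(trials, g), 0.4)      # errors 10,50,44,46,0
  # wrapped difference: 350 is 10 degrees from 0
  expect_equal(polar_error_rate(data.frame(true_idx = 1L, resp_idx = 6L), g), 0)
  # front answered rear
  g2 <- direction_grid(interaural_polar_inverse(c(0, 0), c(0, 180)))
  expect_equal(polar_error_rate(data.frame(true_idx = 1L, resp_idx = 2L), g2), 1)
  expect_equal(polar_error_rate(data.frame(true_idx = c(1L, 2L),
                                           resp_idx = c(1L, 2L)), g2), 0)
  # permutation invariance
  tr <- data.frame(true_idx = c(1L, 1L, 1L), resp_idx = c(2L, 3L, 4L))
  expect_equal(polar_error_rate(tr, g), polar_error_rate(tr[c(3, 1, 2), ], g))
  expect_error(polar_error_rate(tr[0, ], g), "no trials")
})

test_that("trial simulation is seed-deterministic", {
  dec <- decoder_model(hrtf_small, NULL, "ISD")
  a <- simulate_trials(dec, hrtf_small, rep(0, 30), 1:50, seed = 30)
  b <- simulate_trials(dec, hrtf_small, rep(0, 30), 1:50, seed = 30)
  expect_identical(a, b)
  c2 <- simulate_trials(dec, hrtf_small, rep(0, 30), 1:50, seed = 31)
  expect_false(identical(a$resp_idx, c2$resp_idx))
})

test_that("the ripple experiment table aggregates pooled error rates", {
  prior <- build_prior(synth_corpus(fb30, 5000, seed = 32), "synthetic")
  hrtfs <- synth_hrtf_cohort(grid_small, fb30, n_subjects = 2, seed = 33)
  region <- which(region_mask(grid_small))
  conds <- data.frame(depth_db = c(0, 40), density = c(1, 1), phase = 0)
  res <- run_ripple_experiment(hrtfs, prior, c("ISD", "BIN_SG"), conds,
                               region, seed = 34)
  expect_identical(nrow(res), 4L)
  expect_true(all(res$n_trials == 2 * length(region)))
  expect_true(all(res$error_rate >= 0 & res$error_rate <= 1))
  # zero-depth ripple is exactly the flat-spectrum condition
  flat <- ripple_spectrum(fb30, 0, 1, 0)
  dec <- decoder_model(hrtfs[[1]], prior, "BIN_SG")
  t_flat <- simulate_trials(dec, hrtfs[[1]], rep(0, 30), region, seed = 35)
  t_a0 <- simulate_trials(dec, hrtfs[[1]], flat, region, seed = 35)
  expect_identical(t_flat$resp_idx, t_a0$resp_idx)
  # per-subject rows include a pooled row per condition
  res2 <- run_ripple_experiment(hrtfs, prior, "ISD", conds[1, ], region,
                                seed = 36, per_subject = TRUE)
  expect_identical(sum(res2$subject == "pooled"), 1L)
  expect_identical(nrow(res2), 3L)
})

test_that("narrow priors beat ecological priors only on matching stimuli", {
  prior <- build_prior(synth_corpus(fb30, 5000, seed = 37), "synthetic")
  hrtfs <- list(hrtf_small)
  variants <- list(
    narrow = list(representation = "BIN_SG",
                  source = narrow_prior(rep(0, 30), 1)),
    eco = list(representation = "BIN_SG", source = prior))
  res <- run_flat_experiment(hrtfs, variants,
                             dirs_idx = which(region_mask(grid_small)),
                             n_rep = 2, seed = 38)
  m <- tapply(res$mean_gc_error_deg, res$variant, mean)
  expect_lt(m[["narrow"]], m[["eco"]])
})

test_that("interaural-difference decoding is weakest near the midsagittal plane", {
  variants <- list(isd = list(representation = "ISD", source = NULL))
  res <- run_flat_experiment(list(hrtf_small), variants, n_rep = 2, seed = 39)
  near <- abs(res$lateral_deg) <= 20
  far <- abs(res$lateral_deg) >= 50
  expect_gt(mean(res$mean_gc_error_deg[near]), mean(res$mean_gc_error_deg[far]))
})

test_that("response histograms conserve trials and expose the attractor", {
  dec <- decoder_model(hrtf_small, NULL, "ISD")
  tr <- simulate_trials(dec, hrtf_small, rep(0, 30), 1:150, seed = 40)
  rd <- response_distribution(tr, grid_small)
  expect_identical(sum(rd$counts), 150L)
  expect_identical(rd$attractor, which.max(rd$counts))
  # zero noise, matching stimulus: each direction answers itself once
  prior <- build_prior(synth_corpus(fb30, 5000, seed = 41), "synthetic")
  decb <- decoder_model(hrtf_small, prior, "BIN_SG")
  tr0 <- simulate_trials(decb, hrtf_small, prior$mean,
                         seq_len(grid_small$n), noise_draw = FALSE)
  rd0 <- response_distribution(tr0, grid_small)
  expect_identical(rd0$counts, rep(1L, grid_small$n))
  # attractor templates come from the gradient block
  att <- attractor_templates(decb, rd$attractor, ripple_spectrum(fb30, 40, 1))
  expect_length(att$sg_left, 29)
  expect_length(att$sg_stimulus, 29)
  expect_error(attractor_templates(dec, 1), "gradient")
})
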