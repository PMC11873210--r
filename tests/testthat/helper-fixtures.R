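# Shared small fixtures, built once per test run.

fb30 <- make_filterbank(300, 12000, 1)

# modest decoding grid (uniform, lower cone removed) + one synthetic subject
grid_small <- filter_grid(uniform_sphere_grid(300), -45)
hrtf_small <- synth_hrtf(grid_small, fb30, seed = 42)

# symmetric-ears generator settings (used by mirror-symmetry checks)
params_symmetric <- synth_hrtf_params(ear_jitter_erb = 0, depth_jitter_db = 0)

# analytic source prior with known structure (for propagation oracles)
prior_known <- local({
  e <- erb_number(fb30$centre_frequencies_hz)
  cov <- 36 + 64 * exp(-abs(outer(e, e, "-")) / 2)   # level + decaying term
  source_prior(seq(60, 30, length.out = 30), cov, "LOGMAG", "analytic")
})

# draw n samples from a source_prior (columns are samples)
draw_prior <- function(p, n, seed) {
  U <- chol(p$cov + diag(1e-10 * sum(diag(p$cov)), length(p$mean)))
  with_seed <- getFromNamespace("with_seed", "soundloc")
  with_seed(seed, t(matrix(rnorm(n * length(p$mean)), n) %*% U) + p$mean)
}

# a tone at a given frequency, amplitude a, duration dur seconds
tone <- function(freq, fs = 44100, dur = 0.2, a = 0.1)
  a * sin(2 * pi * freq * seq(0, dur - 1 / fs, by = 1 / fs))
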