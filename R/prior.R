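#' Source-spectrum prior
#'
#' A multivariate-Gaussian summary of the spectra (or spectral gradients)
#' of an ensemble of sources: mean vector plus covariance matrix.  It
#' encodes the listener's expectations about source spectra; the observer
#' adds it to the measurement-noise covariance when the chosen feature
#' representation is sensitive to the source spectrum.
#'
#' @param mean Numeric vector (dB for `LOGMAG`, dB/step for `SG`).
#' @param cov Symmetric positive-semidefinite matrix.
#' @param representation `"LOGMAG"` or `"SG"`.
#' @param provenance Free-text label (corpus name, `"synthetic"`,
#'   `"narrow"`, ...).
#' @return Object of class `source_prior`.
#' @export
source_prior <- function(mean, cov, representation = c("LOGMAG", "SG"),
                         provenance = "unspecified") {
  representation <- match.arg(representation)
  cov <- as.matrix(cov)
  mean <- as.numeric(mean)
  if (nrow(cov) != length(mean) || ncol(cov) != length(mean))
    stop("cov dimensions must match mean length")
  if (max(abs(cov - t(cov))) > 1e-9 * max(1, max(abs(cov))))
    stop("cov must be symmetric")
  cov <- (cov + t(cov)) / 2
  ev <- eigen(cov, symmetric = TRUE)
  tr <- sum(diag(cov))
  if (any(ev$values < -1e-8 * max(tr, 1))) {
    warning("clipping negative covariance eigenvalues to zero")
    cov <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
    cov <- (cov + t(cov)) / 2
  }
  structure(list(mean = mean, cov = cov, representation = representation,
                 provenance = provenance),
            class = "source_prior")
}

#' @export
print.source_prior <- function(x, ...) {
  cat(sprintf("source prior (%s, %s): %d dims, mean range [%.1f, %.1f]\n",
              x$representation, x$provenance, length(x$mean),
              min(x$mean), max(x$mean)))
  invisible(x)
}

#' Estimate a source prior from pooled corpus spectra
#'
#' Sample mean and unbiased sample covariance of a pooled set of
#' per-frame log-magnitude spectra, e.g. produced by [chop_corpus()] +
#' [corpus_logmag()] or by [synth_corpus()].
#'
#' @param spectra Matrix with one frame per row, one channel per column
#'   (dB); at least 2 rows.
#' @param provenance Label recorded in the prior.
#' @return A `LOGMAG` [source_prior()].
#' @export
build_prior <- function(spectra, provenance = "corpus") {
  spectra <- as.matrix(spectra)
  if (nrow(spectra) < 2) stop("need at least 2 frames to estimate a covariance")
  source_prior(colMeans(spectra), cov(spectra), "LOGMAG", provenance)
}

#' Spectral-gradient form of a log-magnitude prior
#'
#' Pushes a `LOGMAG` prior through the (linear) first-difference map `D`:
#' mean `D m`, covariance `D C D'`.  Any common-level (rank-one
#' all-ones) component of the covariance is annihilated exactly since
#' `D 1 = 0` -- which is why gradient priors from very different corpora
#' look alike.
#'
#' @param p A `LOGMAG` [source_prior()].
#' @return An `SG` [source_prior()] of dimension N - 1.
#' @export
to_sg_prior <- function(p) {
  stopifnot(inherits(p, "source_prior"))
  if (p$representation != "LOGMAG") stop("expected a LOGMAG prior")
  n <- length(p$mean)
  if (n < 2) stop("need at least 2 channels")
  D <- diff_matrix(n)
  source_prior(as.numeric(D %*% p$mean), D %*% p$cov %*% t(D), "SG",
               p$provenance)
}

#' Mean per-step standard deviation of a gradient prior
#'
#' `sqrt(mean(diag(cov)))` of the SG-domain prior: the typical spectral
#' gradient magnitude (dB/ERB) the listener expects of a source.
#'
#' @param p A [source_prior()]; a `LOGMAG` prior is converted via
#'   [to_sg_prior()] first.
#' @return Scalar, dB per ERB step.
#' @export
sg_prior_std <- function(p) {
  stopifnot(inherits(p, "source_prior"))
  if (p$representation == "LOGMAG") p <- to_sg_prior(p)
  sqrt(mean(diag(p$cov)))
}

#' Narrow ad-hoc prior around a known reference spectrum
#'
#' The prior used when the listener is assumed to know the stimulus
#' spectrum (up to independent per-channel wiggle of sd `sigma_db`):
#' mean equal to the reference, isotropic covariance `sigma_db^2 I`.
#' `sigma_db = 0` is the delta prior of a fully known spectrum.
#'
#' @param reference Per-channel reference spectrum (dB).
#' @param sigma_db Per-channel standard deviation (>= 0).
#' @return A `LOGMAG` [source_prior()] with provenance `"narrow"`.
#' @export
narrow_prior <- function(reference, sigma_db) {
  if (sigma_db < 0) stop("sigma_db must be >= 0")
  source_prior(reference, diag(sigma_db^2, length(reference)), "LOGMAG",
               "narrow")
}

#' Synthetic corpus of source spectra
#'
#' Draws per-frame log-magnitude spectra from a Gaussian emulating the
#' second-order structure of real-world sound corpora: a mean spectrum
#' sloping down with frequency, a large common-level variance (sounds
#' differ wildly in overall level), and channel-to-channel correlations
#' decaying exponentially with ERB distance.  The defaults emulate an
#' environmental-sound ensemble: mean falling ~30 dB from 300 Hz to
#' 12 kHz, 12 dB common-level sd, 8.6 dB channel sd with a 1.5-ERB
#' correlation length (giving an SG-domain std of ~8.5 dB/ERB).
#'
#' @param fb An [make_filterbank()].
#' @param n_frames Number of frames to draw (>= 2).
#' @param slope_db_per_decade Mean-spectrum slope (dB per decade of
#'   frequency; negative = falling).
#' @param level_sd_db Common-level standard deviation (dB).
#' @param channel_sd_db Channel-specific standard deviation (dB).
#' @param corr_length_erb Correlation length of the channel term (ERB);
#'   0 gives independent channels.
#' @param base_level_db Mean level of the first channel (dB).
#' @param seed RNG seed; same seed, same frames.
#' @return Matrix `n_frames` x N of spectra (dB), ready for
#'   [build_prior()].
#' @export
synth_corpus <- function(fb, n_frames = 20000, slope_db_per_decade = -18.7,
                         level_sd_db = 12, channel_sd_db = 8.6,
                         corr_length_erb = 1.5, base_level_db = 60,
                         seed = 1) {
  stopifnot(inherits(fb, "erb_filterbank"))
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (level_sd_db < 0 || channel_sd_db < 0 || corr_length_erb < 0)
    stop("variance parameters must be >= 0")
  cf <- fb$centre_frequencies_hz
  mu <- base_level_db + slope_db_per_decade * log10(cf / cf[1])
  e <- erb_number(cf)
  Rch <- if (corr_length_erb > 0)
    exp(-abs(outer(e, e, "-")) / corr_length_erb) else diag(fb$n_channels)
  Sig <- level_sd_db^2 + channel_sd_db^2 * Rch     # level term = ones matrix
  U <- chol(Sig + diag(1e-10 * sum(diag(Sig)), fb$n_channels))
  with_seed(seed, {
    Z <- matrix(rnorm(n_frames * fb$n_channels), n_frames)
    sweep(Z %*% U, 2, mu, "+")
  })
}

#' Serialize a source prior
#'
#' Writes (or reads) a prior as a JSON container holding the mean,
#' covariance, representation and provenance, optionally with a
#' filterbank descriptor.
#'
#' @param p A [source_prior()].
#' @param path File path.
#' @param fb Optional [make_filterbank()] stored alongside.
#' @export
write_prior_json <- function(p, path, fb = NULL) {
  stopifnot(inherits(p, "source_prior"))
  obj <- list(mean = p$mean, cov = p$cov, representation = p$representation,
              provenance = p$provenance)
  if (!is.null(fb)) obj$filterbank <- unclass(fb)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_prior_json
#' @export
read_prior_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  source_prior(x$mean, x$cov, x$representation, x$provenance)
}
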