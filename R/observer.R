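#' Measurement-noise model
#'
#' Gaussian additive noise on the transformed acoustic input, with
#' variance independent of the input by construction of the jnd/dB
#' coordinates: unit-order noise on the ITD (jnd units) and per-channel
#' noise on each ear's log-magnitude (dB).  Defaults put 1 jnd on the ITD
#' and 1 dB per channel per ear, matching the order of psychoacoustic
#' discrimination thresholds; both are configurable.
#'
#' @param sigma_itd_jnd ITD noise sd in jnd units (> 0).
#' @param sigma_channel_db Per-channel log-magnitude noise sd in dB:
#'   scalar or one value per channel (> 0).
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(sigma_itd_jnd = 1, sigma_channel_db = 1) {
  if (any(sigma_itd_jnd <= 0) || any(sigma_channel_db <= 0))
    stop("noise standard deviations must be > 0")
  structure(list(sigma_itd_jnd = sigma_itd_jnd,
                 sigma_channel_db = sigma_channel_db),
            class = "noise_model")
}

# Per-coordinate noise sd on the stacked raw vector [itd; Xl; Xr].
raw_noise_sd <- function(noise, fb) {
  stopifnot(inherits(noise, "noise_model"))
  s <- rep_len(noise$sigma_channel_db, fb$n_channels)
  c(noise$sigma_itd_jnd, s, s)
}

#' Total feature-space covariance of the observer
#'
#' Assembles the covariance of the Gaussian likelihood for a feature
#' representation: `Sigma = A Sn A' + (A B) Ss (A B)'`, where `A` is the
#' feature map on the stacked raw input, `Sn` the diagonal
#' measurement-noise covariance, `Ss` the source-spectrum prior
#' covariance, and `B` stacks a source spectrum identically onto both
#' ears (`[0; S; S]`).  Structural consequences follow automatically:
#' the source term vanishes exactly for the ISD representation and for
#' the ILD coordinate, while for gradient representations the left and
#' right blocks receive identical source contributions with full
#' cross-ear correlation.
#'
#' @param noise A [noise_model()].
#' @param source A `LOGMAG` [source_prior()], or `NULL` for no source
#'   uncertainty (e.g. the ISD observer).
#' @param fmap A [build_feature_map()] object.
#' @return Symmetric covariance matrix in feature space.
#' @export
assemble_covariance <- function(noise, source, fmap) {
  stopifnot(inherits(fmap, "feature_map"))
  fb <- fmap$fb
  A <- fmap$A
  sd_raw <- raw_noise_sd(noise, fb)
  Sigma <- A %*% (sd_raw^2 * t(A))
  if (!is.null(source)) {
    stopifnot(inherits(source, "source_prior"))
    if (source$representation != "LOGMAG")
      stop("assemble_covariance expects a LOGMAG source prior")
    if (length(source$mean) != fb$n_channels)
      stop("source prior dimension does not match the filterbank")
    N <- fb$n_channels
    B <- rbind(matrix(0, 1, N), diag(N), diag(N))
    J <- A %*% B
    Sigma <- Sigma + J %*% source$cov %*% t(J)
  }
  Sigma <- (Sigma + t(Sigma)) / 2
  ev <- min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8 * sum(diag(Sigma))) stop("assembled covariance is not PSD")
  Sigma
}

#' Direction-indexed feature templates
#'
#' The template for direction theta combines the directional filtering
#' (HRTF log-magnitudes, ITD) with the most likely source spectrum (the
#' prior mean): per-ear template spectrum = HRTF + prior mean in the log
#' domain, ITD coordinate = the jnd-transformed HRTF ITD, all mapped to
#' the feature representation.
#'
#' @param hrtf An [hrtf_set()].
#' @param source A `LOGMAG` [source_prior()] or `NULL` (zero mean
#'   spectrum).
#' @param fmap A [build_feature_map()] object.
#' @param itd_curve Tabulated ITD-to-jnd curve, see [itd_to_jnd()].
#' @return Matrix d x n_directions of feature templates (linear part; no
#'   rectification applied).
#' @export
build_templates <- function(hrtf, source, fmap,
                            itd_curve = default_itd_jnd_curve()) {
  stopifnot(inherits(hrtf, "hrtf_set"), inherits(fmap, "feature_map"))
  if (hrtf$fb$n_channels != fmap$fb$n_channels)
    stop("HRTF and feature map filterbanks disagree")
  mu <- if (is.null(source)) 0 else {
    if (length(source$mean) != hrtf$fb$n_channels)
      stop("source prior dimension does not match the HRTF filterbank")
    source$mean
  }
  raw <- rbind(itd_to_jnd(hrtf$itd_us, itd_curve),
               t(sweep(hrtf$logmag_left, 2, -mu)),
               t(sweep(hrtf$logmag_right, 2, -mu)))
  featurize(fmap, raw)
}

#' Ideal-observer decoder model
#'
#' Assembles everything needed to decode directions from one feature
#' representation: the feature map, per-direction templates, the total
#' covariance (assembled once, factored once -- likelihood evaluation
#' never refactors per trial), and whitened-template caches for fast
#' batch decoding.  For `IPSI_SG`, two reduced sub-models (left-ear and
#' right-ear) are cached and selected per trial by the sign of the
#' measured ITD; for `POS_SG`, templates are rectified here and
#' observations at decode time, with the `BIN_SG` covariance retained.
#'
#' @param hrtf An [hrtf_set()] (already on the decoding grid).
#' @param source A `LOGMAG` [source_prior()] or `NULL` (the ISD observer
#'   needs none).
#' @param representation Feature representation tag, see
#'   [build_feature_map()].
#' @param noise A [noise_model()].
#' @param itd_curve ITD-to-jnd curve.
#' @return Object of class `decoder_model`.
#' @export
decoder_model <- function(hrtf, source, representation,
                          noise = noise_model(),
                          itd_curve = default_itd_jnd_curve()) {
  fmap <- build_feature_map(representation, hrtf$fb)
  Sigma <- assemble_covariance(noise, if (representation == "ISD") NULL else source,
                               fmap)
  Tm <- build_templates(hrtf, source, fmap, itd_curve)
  if (fmap$postnonlinearity == "rectify")
    Tm[fmap$sg_rows, ] <- pmax(Tm[fmap$sg_rows, ], 0)
  chol_cache <- function(S, Tmat) {
    S <- (S + t(S)) / 2
    U <- tryCatch(chol(S), error = function(e) {
      chol(S + diag(1e-10 * sum(diag(S)), nrow(S)))   # jittered fallback
    })
    W <- backsolve(U, Tmat, transpose = TRUE)
    list(U = U, W = W, wnorm = colSums(W^2),
         logdet = 2 * sum(log(diag(U))), d = nrow(S))
  }
  model <- list(representation = representation, fmap = fmap,
                grid = hrtf$grid, fb = hrtf$fb, noise = noise,
                source = source, itd_curve = itd_curve,
                Sigma = Sigma, templates = Tm)
  if (representation == "IPSI_SG") {
    N <- hrtf$fb$n_channels
    idx <- list(left = c(1L, 2L, fmap$left_rows),
                right = c(1L, 2L, fmap$right_rows))
    model$sub <- lapply(idx, function(ii)
      c(list(idx = ii), chol_cache(Sigma[ii, ii], Tm[ii, , drop = FALSE])))
  } else {
    model <- c(model, chol_cache(Sigma, Tm))
  }
  structure(model, class = "decoder_model")
}

#' @export
print.decoder_model <- function(x, ...) {
  cat(sprintf("decoder model %s: %d directions, feature dim %d\n",
              x$representation, x$grid$n, nrow(x$templates)))
  invisible(x)
}

#' Per-direction Gaussian log-likelihood
#'
#' Evaluates `log P(X | theta)` over the whole direction grid for one
#' feature vector, through the cached Cholesky factorization:
#' `-(1/2)(x - T)' Sigma^-1 (x - T) - (1/2) log det(2 pi Sigma)`.  For
#' `POS_SG` the observation is rectified first; for `IPSI_SG` the
#' contralateral gradient block is dropped (sub-model keyed on the sign
#' of the measured ITD) before evaluation.
#'
#' @param x Feature vector (linear-part features, as from [featurize()]).
#' @param model A [decoder_model()].
#' @return Numeric vector of log-densities, one per grid direction.
#' @export
log_likelihood <- function(x, model) {
  stopifnot(inherits(model, "decoder_model"))
  x <- as.numeric(x)
  if (length(x) != nrow(model$templates))
    stop("feature vector dimension does not match the model")
  if (model$representation == "IPSI_SG") {
    sub <- if (x[1] >= 0) model$sub$left else model$sub$right
    xs <- x[sub$idx]
    wx <- backsolve(sub$U, xs, transpose = TRUE)
    q <- colSums((sub$W - wx)^2)
    -0.5 * q - 0.5 * sub$logdet - 0.5 * sub$d * log(2 * pi)
  } else {
    if (model$fmap$postnonlinearity == "rectify")
      x[model$fmap$sg_rows] <- pmax(x[model$fmap$sg_rows], 0)
    wx <- backsolve(model$U, x, transpose = TRUE)
    q <- colSums((model$W - wx)^2)
    -0.5 * q - 0.5 * model$logdet - 0.5 * model$d * log(2 * pi)
  }
}

#' Posterior over directions
#'
#' Normalizes per-direction log-likelihoods (plus an optional non-uniform
#' spatial prior weight per direction) into a posterior probability
#' vector, with log-sum-exp stabilization.  The spatial prior defaults to
#' uniform.
#'
#' @param loglik Per-direction log-likelihood vector.
#' @param spatial_prior Optional per-direction nonnegative weights.
#' @return Object of class `posterior`: numeric probability vector
#'   summing to 1.
#' @export
posterior <- function(loglik, spatial_prior = NULL) {
  if (any(is.na(loglik)) || any(loglik == Inf)) stop("non-finite log-likelihoods")
  lp <- loglik
  if (!is.null(spatial_prior)) {
    if (length(spatial_prior) != length(loglik))
      stop("spatial prior length mismatch")
    if (any(spatial_prior < 0)) stop("spatial prior weights must be >= 0")
    lp <- lp + log(spatial_prior)
  }
  m <- max(lp)
  if (!is.finite(m)) stop("posterior undefined: all directions have zero likelihood")
  p <- exp(lp - m)
  structure(p / sum(p), class = "posterior")
}

#' Maximum a posteriori direction
#'
#' Index of the posterior mode; ties broken toward the lowest index.
#'
#' @param p A [posterior()] (or any probability vector).
#' @return Integer direction index.
#' @export
map_estimate <- function(p) which.max(p)

# Batch MAP decoding of feature-vector columns; returns response indices.
decode_map <- function(model, X) {
  stopifnot(inherits(model, "decoder_model"))
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  m <- ncol(X)
  resp <- integer(m)
  if (model$representation == "IPSI_SG") {
    for (side in c("left", "right")) {
      sel <- if (side == "left") X[1, ] >= 0 else X[1, ] < 0
      if (!any(sel)) next
      sub <- model$sub[[side]]
      WX <- backsolve(sub$U, X[sub$idx, sel, drop = FALSE], transpose = TRUE)
      score <- crossprod(sub$W, WX) - 0.5 * sub$wnorm
      resp[sel] <- max.col(t(score), ties.method = "first")
    }
  } else {
    if (model$fmap$postnonlinearity == "rectify")
      X[model$fmap$sg_rows, ] <- pmax(X[model$fmap$sg_rows, ], 0)
    WX <- backsolve(model$U, X, transpose = TRUE)
    score <- crossprod(model$W, WX) - 0.5 * model$wnorm
    resp <- max.col(t(score), ties.method = "first")
  }
  resp
}
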