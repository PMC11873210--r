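#' Broadband interaural level difference
#'
#' Mean over channels of the left-minus-right log-magnitude difference,
#' `ILD = (1/N) sum_i (Xl_i - Xr_i)` in dB.
#'
#' @param xl,xr Per-channel log-magnitude vectors (dB) of equal length.
#' @return Scalar ILD in dB.
#' @export
ild <- function(xl, xr) {
  if (length(xl) != length(xr)) stop("ears have mismatched filterbanks")
  mean(xl - xr)
}

#' Spectral gradient
#'
#' First difference of a log-magnitude spectrum across neighbouring ERB
#' channels: entry i is `x[i+1] - x[i]`, in dB per channel step.
#'
#' @param x Per-channel log-magnitude vector (length >= 2).
#' @return Vector of length `length(x) - 1`.
#' @export
sg <- function(x) {
  if (length(x) < 2) stop("spectral gradient needs at least two channels")
  diff(x)
}

#' Interaural spectral difference
#'
#' Channelwise left-minus-right log-magnitude.  Because both ears receive
#' the same source spectrum, the subtraction removes it: the ISD carries
#' only source-invariant directional information.
#'
#' @inheritParams ild
#' @return Vector of per-channel differences (dB).
#' @export
isd <- function(xl, xr) {
  if (length(xl) != length(xr)) stop("ears have mismatched filterbanks")
  xl - xr
}

#' Rectified (positive) spectral gradient
#'
#' Entrywise `max(0, g)`: keeps only the positive gradient values, the
#' hypothesized physiological code in which negative slopes are not
#' relayed.  Idempotent.
#'
#' @param g A gradient vector (or matrix of gradient columns).
#' @return Same shape as `g`, rectified.
#' @export
positive_sg <- function(g) pmax(g, 0)

#' Choose the ipsilateral ear's gradient
#'
#' Selects the spectral gradient of the ear toward which the measured ITD
#' points: left if the ITD is positive (left ear leads), right if
#' negative, and left by convention at exactly zero (a measure-zero event
#' under continuous noise).
#'
#' @param g_left,g_right Gradient vectors.
#' @param measured_itd_jnd Measured ITD (any monotone unit; only the sign
#'   is used).
#' @return One of the two gradient vectors.
#' @export
select_ipsilateral <- function(g_left, g_right, measured_itd_jnd) {
  if (measured_itd_jnd >= 0) g_left else g_right
}

# first-difference matrix: (N-1) x N, rows (-1, +1)
diff_matrix <- function(n) {
  D <- matrix(0, n - 1, n)
  D[cbind(seq_len(n - 1), seq_len(n - 1))] <- -1
  D[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- 1
  D
}

#' Feature maps on the stacked acoustic input
#'
#' Every representation used by the observer is a linear map `A` applied
#' to the stacked raw vector `[itd_jnd; Xl; Xr]` (length 2N + 1), with an
#' optional post-nonlinearity:
#'
#' * `LOGMAG`: identity (ITD + both log-magnitude spectra).
#' * `ISD`: ITD and the channelwise left-minus-right difference.
#' * `BIN_SG`: ITD, broadband ILD, and both ears' spectral gradients.
#' * `POS_SG`: the `BIN_SG` map followed by rectification of the
#'   gradient entries (applied to observations and templates alike).
#' * `IPSI_SG`: the `BIN_SG` map followed by selection of the
#'   ipsilateral gradient block keyed on the sign of the measured ITD.
#'
#' Because the maps are linear, Gaussian likelihoods and priors propagate
#' through them exactly (`A Sigma A'`).
#'
#' @param representation One of `"LOGMAG"`, `"ISD"`, `"BIN_SG"`,
#'   `"POS_SG"`, `"IPSI_SG"`.
#' @param fb An [make_filterbank()].
#' @return An object of class `feature_map`: list with `representation`,
#'   the matrix `A`, `postnonlinearity` (`"none"`, `"rectify"`,
#'   `"ipsilateral-select"`), row-index bookkeeping (`itd_row`,
#'   `ild_row`, `sg_rows`, `left_rows`, `right_rows`) and `fb`.
#' @export
build_feature_map <- function(representation, fb) {
  stopifnot(inherits(fb, "erb_filterbank"))
  reps <- c("LOGMAG", "ISD", "BIN_SG", "POS_SG", "IPSI_SG")
  if (!representation %in% reps)
    stop("unknown representation tag: '", representation, "' (expected one of ",
         paste(reps, collapse = ", "), ")")
  N <- fb$n_channels
  r <- 2 * N + 1
  itd_sel <- matrix(0, 1, r); itd_sel[1, 1] <- 1
  out <- list(representation = representation, fb = fb, itd_row = 1L,
              ild_row = NA_integer_, sg_rows = integer(0),
              left_rows = integer(0), right_rows = integer(0),
              postnonlinearity = "none")
  if (representation == "LOGMAG") {
    out$A <- diag(r)
  } else if (representation == "ISD") {
    A <- matrix(0, N + 1, r)
    A[1, 1] <- 1
    A[2:(N + 1), 2:(N + 1)] <- diag(N)
    A[2:(N + 1), (N + 2):r] <- -diag(N)
    out$A <- A
  } else {                                  # BIN_SG family
    D <- diff_matrix(N)
    A <- matrix(0, 2 + 2 * (N - 1), r)
    A[1, 1] <- 1
    A[2, 2:(N + 1)] <- 1 / N
    A[2, (N + 2):r] <- -1 / N
    A[3:(N + 1), 2:(N + 1)] <- D
    A[(N + 2):(2 * N), (N + 2):r] <- D
    out$A <- A
    out$ild_row <- 2L
    out$left_rows <- 3:(N + 1)
    out$right_rows <- (N + 2):(2 * N)
    out$sg_rows <- c(out$left_rows, out$right_rows)
    if (representation == "POS_SG") out$postnonlinearity <- "rectify"
    if (representation == "IPSI_SG") out$postnonlinearity <- "ipsilateral-select"
  }
  class(out) <- "feature_map"
  out
}

#' @export
print.feature_map <- function(x, ...) {
  cat(sprintf("feature map %s: %d x %d, postnonlinearity %s\n",
              x$representation, nrow(x$A), ncol(x$A), x$postnonlinearity))
  invisible(x)
}

#' Apply a feature map to stacked raw vectors
#'
#' Computes the linear part of the feature transform, `A %*% raw`.  The
#' post-nonlinearity (rectification, ipsilateral selection) is applied by
#' the decoder, not here, so that covariance propagation stays exact for
#' the linear part.
#'
#' @param fmap A [build_feature_map()] object.
#' @param raw Stacked raw vector `[itd_jnd; Xl; Xr]` (length 2N + 1) or a
#'   matrix with such vectors in columns.
#' @return Feature vector/matrix (features in rows).
#' @export
featurize <- function(fmap, raw) {
  stopifnot(inherits(fmap, "feature_map"))
  if (is.vector(raw)) raw <- matrix(raw, ncol = 1)
  if (nrow(raw) != ncol(fmap$A))
    stop("raw vector length does not match the feature map")
  fmap$A %*% raw
}

#' Invertible spectral contrast map
#'
#' The linear map from the stacked binaural spectrum `[Xl; Xr]` (length
#' 2N) to `[overall level; ILD; dXl; dXr]` (also length 2N).  It is full
#' rank, which is what makes the gradient representation
#' information-equivalent to the raw binaural log-magnitudes whenever the
#' overall level carries no directional information.
#'
#' @param fb An [make_filterbank()].
#' @return A 2N x 2N matrix.
#' @export
spectral_contrast_map <- function(fb) {
  N <- fb$n_channels
  D <- diff_matrix(N)
  M <- matrix(0, 2 * N, 2 * N)
  M[1, ] <- 1 / (2 * N)                     # overall level
  M[2, 1:N] <- 1 / N; M[2, (N + 1):(2 * N)] <- -1 / N
  M[3:(N + 1), 1:N] <- D
  M[(N + 2):(2 * N), (N + 1):(2 * N)] <- D
  M
}
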