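#' ERB-number scale
#'
#' Converts frequency in Hz to the ERB-number scale of Glasberg & Moore,
#' `E(f) = 21.4 log10(0.00437 f + 1)`, on which auditory filter centre
#' frequencies are equally spaced.  `erb_to_hz()` is the exact inverse.
#'
#' @param f Frequencies in Hz (vectorized, must be >= 0).
#' @param e ERB-numbers (vectorized, must be >= 0).
#' @return Numeric vector of ERB-numbers (dimensionless), or Hz for
#'   `erb_to_hz()`.
#' @examples
#' erb_number(1000)           # ~15.62
#' erb_to_hz(erb_number(440)) # 440
#' @export
erb_number <- function(f) {
  if (any(!is.finite(f)) || any(f < 0)) stop("frequencies must be finite and >= 0")
  21.4 * log10(0.00437 * f + 1)
}

#' @rdname erb_number
#' @export
erb_to_hz <- function(e) {
  if (any(!is.finite(e)) || any(e < 0)) stop("ERB-numbers must be finite and >= 0")
  (10^(e / 21.4) - 1) / 0.00437
}

#' ERB-spaced auditory filterbank
#'
#' Builds the discrete frequency axis on which all spectra in the model
#' live: centre frequencies equally spaced on the ERB-number scale, from
#' `f_lo` upward without exceeding `f_hi`.  Each channel owns a rectangular
#' band one `spacing_erb` wide (in ERB units) centred on its centre
#' frequency.  The default 300 Hz--12 kHz span at 1-ERB spacing yields 30
#' channels.
#'
#' @param f_lo,f_hi Band edges in Hz, `0 < f_lo < f_hi`.
#' @param spacing_erb Channel spacing in ERB units (> 0).
#' @return An object of class `erb_filterbank`: list with
#'   `centre_frequencies_hz`, `spacing_erb`, `n_channels`, and per-channel
#'   band edges `band_lo_hz`, `band_hi_hz`.
#' @examples
#' fb <- make_filterbank(300, 12000, 1)
#' fb$n_channels  # 30
#' @export
make_filterbank <- function(f_lo = 300, f_hi = 12000, spacing_erb = 1) {
  stopifnot(length(f_lo) == 1, length(f_hi) == 1, length(spacing_erb) == 1)
  if (!(f_lo > 0 && f_hi > f_lo)) stop("need 0 < f_lo < f_hi")
  if (spacing_erb <= 0) stop("spacing_erb must be > 0")
  e_lo <- erb_number(f_lo)
  e_hi <- erb_number(f_hi)
  n <- floor((e_hi - e_lo) / spacing_erb + 1e-12) + 1L
  if (n < 1) stop("empty band: no channel fits between f_lo and f_hi")
  e_c <- e_lo + spacing_erb * (seq_len(n) - 1)
  fb <- structure(list(
    centre_frequencies_hz = erb_to_hz(e_c),
    spacing_erb = spacing_erb,
    n_channels = as.integer(n),
    band_lo_hz = erb_to_hz(pmax(e_c - spacing_erb / 2, 0)),
    band_hi_hz = erb_to_hz(e_c + spacing_erb / 2)
  ), class = "erb_filterbank")
  fb
}

#' @export
print.erb_filterbank <- function(x, ...) {
  cat(sprintf("ERB filterbank: %d channels, %.0f-%.0f Hz, %.3g ERB spacing\n",
              x$n_channels, x$centre_frequencies_hz[1],
              x$centre_frequencies_hz[x$n_channels], x$spacing_erb))
  invisible(x)
}

#' @rdname make_filterbank
#' @param fb An `erb_filterbank`.
#' @param path File path for the JSON descriptor.
#' @export
write_filterbank_json <- function(fb, path) {
  stopifnot(inherits(fb, "erb_filterbank"))
  jsonlite::write_json(unclass(fb), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname make_filterbank
#' @export
read_filterbank_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(centre_frequencies_hz = as.numeric(x$centre_frequencies_hz),
                 spacing_erb = as.numeric(x$spacing_erb),
                 n_channels = as.integer(x$n_channels),
                 band_lo_hz = as.numeric(x$band_lo_hz),
                 band_hi_hz = as.numeric(x$band_hi_hz)),
            class = "erb_filterbank")
}

#' Per-channel log-magnitude spectrum of an audio frame
#'
#' Computes one log-magnitude value per filterbank channel from a frame of
#' audio samples.  The frame is windowed, transformed, and the periodogram
#' is accumulated over each channel's rectangular ERB-wide band.  Two
#' normalizations are available: `"power"` integrates band power (used for
#' corpus frames, so a white signal rises with channel bandwidth), while
#' `"density"` averages squared magnitude over the band (used for transfer
#' functions such as HRIRs, where the value estimates `20 log10 |H(fc)|`).
#'
#' @param x Numeric vector of audio samples (a single frame).
#' @param fs Sample rate in Hz; must exceed twice the highest band edge.
#' @param fb An [make_filterbank()] object.
#' @param window `"hann"` (default) or `"rect"`.
#' @param mode `"power"` or `"density"` (see above).
#' @param n_fft Optional FFT length >= `length(x)` (zero-padded); defaults
#'   to the frame length.
#' @param floor_db Lower clamp for channel values in dB, so silence maps to
#'   a finite floor instead of -Inf.
#' @return Numeric vector of length `fb$n_channels` (dB).
#' @export
frame_logmag <- function(x, fs, fb, window = c("hann", "rect"),
                         mode = c("power", "density"), n_fft = NULL,
                         floor_db = -120) {
  window <- match.arg(window)
  mode <- match.arg(mode)
  stopifnot(inherits(fb, "erb_filterbank"))
  n <- length(x)
  if (n < 1) stop("empty frame")
  if (fs <= 2 * fb$band_hi_hz[fb$n_channels])
    stop("sample rate too low for the filterbank's highest band")
  if (is.null(n_fft)) n_fft <- n
  if (n_fft < n) stop("n_fft must be >= frame length")
  w <- if (window == "hann") 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1)) else rep(1, n)
  xw <- c(x * w, rep(0, n_fft - n))
  X2 <- Mod(fft(xw))^2
  k <- 0:(floor(n_fft / 2))          # one-sided bins
  f <- k * fs / n_fft
  df <- fs / n_fft
  out <- numeric(fb$n_channels)
  for (i in seq_len(fb$n_channels)) {
    in_band <- which(f >= fb$band_lo_hz[i] & f < fb$band_hi_hz[i])
    if (length(in_band) == 0)                     # frame too short: nearest bin
      in_band <- which.min(abs(f - fb$centre_frequencies_hz[i]))
    bins <- X2[in_band]                            # (k index offset by 1)
    if (mode == "density") {
      val <- mean(bins)
    } else {
      psd <- 2 * bins / (fs * sum(w^2))            # one-sided PSD estimate
      val <- sum(psd) * df
    }
    out[i] <- if (val > 0) 10 * log10(val) else -Inf
  }
  pmax(out, floor_db)
}

#' Chop audio files into fixed-length analysis frames
#'
#' Splits each WAV file into consecutive non-overlapping frames of exactly
#' `frame_s` seconds (trailing remainder discarded).  Near-silent frames
#' (RMS below `min_rms_dbfs` relative to full scale) are dropped, and
#' unreadable files are skipped with a warning rather than aborting the
#' corpus scan.
#'
#' @param files Character vector of WAV file paths.
#' @param frame_s Frame length in seconds (> 0); the corpus analyses here
#'   use 0.2 s.
#' @param min_rms_dbfs Energy threshold in dB full scale; frames below it
#'   are discarded.  Use `-Inf` to keep everything.
#' @return List of frames; each frame is a list with `samples`, `fs`,
#'   `file`, `frame_index`.
#' @seealso [corpus_logmag()] to turn frames into a spectrum matrix.
#' @export
chop_corpus <- function(files, frame_s = 0.2, min_rms_dbfs = -60) {
  if (frame_s <= 0) stop("frame_s must be > 0")
  frames <- list()
  for (path in files) {
    wav <- tryCatch(read_wav(path), error = function(e) {
      warning(sprintf("skipping unreadable file '%s': %s", path, conditionMessage(e)))
      NULL
    })
    if (is.null(wav)) next
    nper <- floor(frame_s * wav$fs)
    nfr <- floor(length(wav$samples) / nper)
    if (nfr < 1) next
    for (j in seq_len(nfr)) {
      seg <- wav$samples[((j - 1) * nper + 1):(j * nper)]
      rms <- sqrt(mean(seg^2))
      if (20 * log10(max(rms, 1e-12)) < min_rms_dbfs) next
      frames[[length(frames) + 1L]] <-
        list(samples = seg, fs = wav$fs, file = path, frame_index = j)
    }
  }
  frames
}

#' Log-magnitude spectra for a list of frames
#'
#' Applies [frame_logmag()] to every frame returned by [chop_corpus()].
#'
#' @param frames List of frames from [chop_corpus()].
#' @param fb An [make_filterbank()] object.
#' @param ... Passed on to [frame_logmag()].
#' @return Matrix with one row per frame and one column per channel (dB).
#' @export
corpus_logmag <- function(frames, fb, ...) {
  if (length(frames) == 0) stop("no frames")
  t(vapply(frames, function(fr) frame_logmag(fr$samples, fr$fs, fb, ...),
           numeric(fb$n_channels)))
}
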