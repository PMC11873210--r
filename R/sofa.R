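# SOFA (SimpleFreeFieldHRIR) input/output.
#
# SOFA files are netCDF-4 containers; they are read and written through a
# small Python helper (inst/python/sofa_json.py, using h5py) that converts
# to/from a JSON exchange object.  The acoustic processing -- impulse
# responses to per-channel log-magnitudes, ITD extraction -- happens here.

sofa_python <- function() {
  for (cand in c("python3", "python")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(p)
  }
  stop("no python interpreter found on PATH (needed for SOFA I/O)")
}

sofa_bridge <- function(mode, from, to) {
  helper <- system.file("python", "sofa_json.py", package = "soundloc")
  if (!nzchar(helper)) stop("bundled sofa_json.py helper not found")
  out <- suppressWarnings(
    system2(sofa_python(), c(shQuote(helper), mode, shQuote(from), shQuote(to)),
            stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("SOFA ", mode, " failed: ", paste(out, collapse = " "))
  invisible(to)
}

# FFT-based integer-factor upsampling of a real signal.
upsample_fft <- function(x, factor = 8L) {
  n <- length(x)
  X <- fft(x)
  m <- n * factor
  X2 <- complex(m)
  h <- floor(n / 2)
  X2[1:(h + 1)] <- X[1:(h + 1)]
  if (h >= 1) X2[(m - h + 2):m] <- X[(n - h + 2):n]
  if (n %% 2 == 0) {                       # split the Nyquist bin
    X2[h + 1] <- X[h + 1] / 2
    X2[m - h + 1] <- Conj(X[h + 1]) / 2
  }
  Re(fft(X2, inverse = TRUE)) * factor / m
}

# Onset time (seconds) of an impulse response: first crossing of
# `threshold` x peak magnitude, on an 8x upsampled envelope, with linear
# interpolation of the crossing.
ir_onset_s <- function(ir, fs, threshold = 0.1, factor = 8L) {
  up <- upsample_fft(ir, factor)
  a <- abs(up)
  thr <- threshold * max(a)
  i <- which(a >= thr)[1]
  if (is.na(i)) return(0)
  if (i == 1) return(0)
  frac <- (thr - a[i - 1]) / (a[i] - a[i - 1])
  ((i - 2) + frac) / (fs * factor)
}

# Interaural delay (seconds, positive = left leads) by cross-correlation
# with FFT upsampling and parabolic peak interpolation.
ir_xcorr_delay_s <- function(left, right, fs, factor = 16L) {
  n <- length(left)
  c_raw <- Re(fft(fft(left) * Conj(fft(right)), inverse = TRUE)) / n
  cu <- upsample_fft(c_raw, factor)
  m <- length(cu)
  k <- which.max(cu)
  km <- if (k == 1) m else k - 1
  kp <- if (k == m) 1 else k + 1
  denom <- cu[km] - 2 * cu[k] + cu[kp]
  delta <- if (abs(denom) > 1e-300) 0.5 * (cu[km] - cu[kp]) / denom else 0
  lag <- (k - 1) + delta                    # circular lag in upsampled samples
  if (lag > m / 2) lag <- lag - m
  # positive lag: left delayed relative to right => right leads => itd < 0
  -lag / (fs * factor)
}

#' Read a SOFA HRTF file
#'
#' Loads a SimpleFreeFieldHRIR SOFA file, converts the impulse responses
#' to per-channel log-magnitudes on the given ERB filterbank (rectangular
#' window, band-averaged squared magnitude, i.e. a transfer-function
#' estimate in dB), extracts a scalar ITD per direction, and converts the
#' source positions to the internal interaural-polar convention.
#'
#' @param path Path to a .sofa file.
#' @param fb An [make_filterbank()].
#' @param itd_method `"onset"` (10%-of-peak onset difference, default) or
#'   `"xcorr"` (cross-correlation peak).
#' @param subject_id Label; defaults to the file name.
#' @return An [hrtf_set()].
#' @export
load_sofa <- function(path, fb, itd_method = c("onset", "xcorr"),
                      subject_id = basename(path)) {
  itd_method <- match.arg(itd_method)
  stopifnot(inherits(fb, "erb_filterbank"))
  js <- tempfile(fileext = ".json")
  on.exit(unlink(js))
  sofa_bridge("read", path, js)
  obj <- jsonlite::read_json(js, simplifyVector = TRUE)
  ir <- obj$ir                              # M x R x N array
  if (length(dim(ir)) != 3 || dim(ir)[2] < 2)
    stop("Data.IR must have at least two receivers (left, right)")
  fs <- obj$fs
  pos <- as.matrix(obj$source_position)
  azi <- pos[, 1] * pi / 180; ele <- pos[, 2] * pi / 180
  grid <- direction_grid(cbind(cos(ele) * cos(azi), cos(ele) * sin(azi), sin(ele)))
  m <- dim(ir)[1]
  n_fft <- max(4096L, dim(ir)[3])
  N <- fb$n_channels
  L <- matrix(0, m, N); R <- matrix(0, m, N); itd <- numeric(m)
  for (i in seq_len(m)) {
    irl <- ir[i, 1, ]; irr <- ir[i, 2, ]
    L[i, ] <- frame_logmag(irl, fs, fb, window = "rect", mode = "density",
                           n_fft = n_fft)
    R[i, ] <- frame_logmag(irr, fs, fb, window = "rect", mode = "density",
                           n_fft = n_fft)
    itd[i] <- 1e6 * if (itd_method == "onset")
      ir_onset_s(irr, fs) - ir_onset_s(irl, fs)
    else ir_xcorr_delay_s(irl, irr, fs)
  }
  hrtf_set(grid, L, R, itd, fb, subject_id)
}

#' Write an HRTF set to a SOFA file
#'
#' Minimal SimpleFreeFieldHRIR writer, intended for fixtures: each
#' direction's impulse response pair is synthesized from the per-channel
#' log-magnitudes (piecewise-constant magnitude over each ERB band) with a
#' pure interaural delay realizing the stored ITD around a common base
#' delay.  Reading such a file back with [load_sofa()] on the same
#' filterbank reproduces the log-magnitudes exactly and the ITD to within
#' a few microseconds.
#'
#' @param hrtf An [hrtf_set()].
#' @param path Output .sofa path.
#' @param fs Sample rate of the synthesized responses, Hz.
#' @param n_fft Impulse-response length in samples.
#' @param base_delay_s Common delay of both ears, seconds.
#' @param phase `"minimum"` (default): minimum-phase responses plus pure
#'   delay, with a realistic causal energy onset; `"linear"`: zero-phase
#'   pulses plus pure delay, for which cross-correlation ITD read-back is
#'   exact to sub-microsecond.
#' @export
write_sofa <- function(hrtf, path, fs = 44100, n_fft = 4096,
                       base_delay_s = 0.002, phase = c("minimum", "linear")) {
  phase <- match.arg(phase)
  stopifnot(inherits(hrtf, "hrtf_set"))
  fb <- hrtf$fb
  f <- (0:(n_fft - 1)) * fs / n_fft
  half <- f <= fs / 2
  # map each one-sided bin to a channel (in-band exact, else nearest)
  ch <- integer(n_fft)
  for (k in which(half)) {
    hit <- which(f[k] >= fb$band_lo_hz & f[k] < fb$band_hi_hz)
    ch[k] <- if (length(hit)) hit[1] else
      which.min(abs(fb$centre_frequencies_hz - f[k]))
  }
  make_ir <- function(db_vals, tau) {
    # minimum-phase response with the piecewise-per-band magnitude,
    # delayed by tau: energy is concentrated at the delay, so both the
    # magnitude and onset-based ITD survive a read-back
    idx <- which(half)
    mag_half <- 10^(db_vals[ch[idx]] / 20)
    h <- length(idx)                                 # n_fft/2 + 1 bins
    Hm <- if (phase == "minimum") {
      mag_full <- c(mag_half, rev(mag_half[2:(h - 1)]))
      cep <- Re(fft(log(mag_full), inverse = TRUE)) / n_fft
      cep[2:(h - 1)] <- 2 * cep[2:(h - 1)]
      cep[(h + 1):n_fft] <- 0
      exp(fft(cep))[idx]
    } else mag_half
    H <- complex(n_fft)
    H[idx] <- Hm * exp(-2i * pi * f[idx] * tau)
    if (n_fft %% 2 == 0) H[n_fft / 2 + 1] <- Re(H[n_fft / 2 + 1])
    if (n_fft > 2) {
      tail_idx <- (floor(n_fft / 2) + 2):n_fft
      H[tail_idx] <- Conj(H[n_fft - tail_idx + 2])
    }
    Re(fft(H, inverse = TRUE)) / n_fft
  }
  m <- hrtf$grid$n
  ir <- array(0, c(m, 2, n_fft))
  for (i in seq_len(m)) {
    d <- hrtf$itd_us[i] * 1e-6
    ir[i, 1, ] <- make_ir(hrtf$logmag_left[i, ], base_delay_s - d / 2)
    ir[i, 2, ] <- make_ir(hrtf$logmag_right[i, ], base_delay_s + d / 2)
  }
  v <- hrtf$grid$unit_vectors
  azi <- (atan2(v[, 2], v[, 1]) * 180 / pi) %% 360
  ele <- asin(pmin(pmax(v[, 3], -1), 1)) * 180 / pi
  js <- tempfile(fileext = ".json")
  on.exit(unlink(js))
  jsonlite::write_json(
    list(fs = fs, source_position = cbind(azi, ele, rep(1.2, m)), ir = ir),
    js, digits = NA, auto_unbox = TRUE)
  sofa_bridge("write", js, path)
  invisible(path)
}
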