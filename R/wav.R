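#' Read a RIFF/WAVE audio file
#'
#' Minimal WAV reader supporting integer PCM (16/24/32 bit), IEEE float
#' (32/64 bit) and the WAVE_FORMAT_EXTENSIBLE wrapper around either.
#' Multi-channel files are converted to mono by channel averaging; samples
#' are returned as doubles scaled to [-1, 1] full scale.
#'
#' @param path Path to a .wav file.
#' @return List with `samples` (numeric vector, mono), `fs` (sample rate,
#'   Hz) and `n_channels` (channel count before averaging).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")   # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(sz) == 0) break
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        format = readBin(raw[1:2], "integer", 1, 2, signed = FALSE, endian = "little"),
        n_channels = readBin(raw[3:4], "integer", 1, 2, signed = FALSE, endian = "little"),
        fs = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1, 2, signed = FALSE, endian = "little")
      )
      if (fmt$format == 65534 && sz >= 40)           # extensible: subformat GUID
        fmt$format <- readBin(raw[25:26], "integer", 1, 2, signed = FALSE, endian = "little")
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz + sz %% 2)              # skip (chunks are word-aligned)
      next
    }
    if (sz %% 2 == 1) readBin(con, "raw", 1)
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("missing fmt chunk in ", path)
  if (is.null(data_raw)) stop("missing data chunk in ", path)
  bytes <- fmt$bits / 8
  n_total <- floor(length(data_raw) / bytes)
  x <- if (fmt$format == 1) {
    if (fmt$bits == 16) {
      readBin(data_raw, "integer", n_total, 2, signed = TRUE, endian = "little") / 32768
    } else if (fmt$bits == 24) {
      m <- matrix(as.integer(data_raw[seq_len(n_total * 3)]), nrow = 3)
      v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
      ifelse(v >= 8388608, v - 16777216, v) / 8388608
    } else if (fmt$bits == 32) {
      readBin(data_raw, "integer", n_total, 4, endian = "little") / 2147483648
    } else stop("unsupported PCM bit depth: ", fmt$bits)
  } else if (fmt$format == 3) {
    readBin(data_raw, "double", n_total, bytes, endian = "little")
  } else stop("unsupported WAV format code: ", fmt$format)
  nc <- fmt$n_channels
  if (nc > 1) {
    n_frames <- floor(length(x) / nc)
    x <- colMeans(matrix(x[seq_len(n_frames * nc)], nrow = nc))
  }
  list(samples = as.numeric(x), fs = fmt$fs, n_channels = as.integer(nc))
}

#' Write a RIFF/WAVE audio file
#'
#' Counterpart of [read_wav()], used mainly to build test fixtures and to
#' export synthetic corpora.  Mono or multi-channel (`x` a vector or a
#' channels-in-columns matrix); samples are clipped to [-1, 1] for PCM.
#'
#' @param x Numeric vector (mono) or matrix (one column per channel).
#' @param fs Sample rate in Hz.
#' @param path Output path.
#' @param bits 16 (integer PCM) or 32 (IEEE float).
#' @export
write_wav <- function(x, fs, path, bits = 16) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  nc <- ncol(x)
  inter <- as.numeric(t(x))                          # interleave channels
  fmt_code <- if (bits == 32) 3L else 1L
  bytes <- bits / 8
  data_size <- length(inter) * bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(fmt_code, con, 2, endian = "little")
  writeBin(as.integer(nc), con, 2, endian = "little")
  writeBin(as.integer(fs), con, 4, endian = "little")
  writeBin(as.integer(fs * nc * bytes), con, 4, endian = "little")
  writeBin(as.integer(nc * bytes), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bits == 16) {
    writeBin(as.integer(round(pmin(pmax(inter, -1), 1) * 32767)), con, 2, endian = "little")
  } else {
    writeBin(inter, con, 4, endian = "little")
  }
  invisible(path)
}
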