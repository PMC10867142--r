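#' Read a RIFF/WAVE PCM file
#'
#' Minimal reader for uncompressed PCM WAV files (the canonical field format:
#' 44.1 kHz, 16-bit). Returns samples scaled to `[-1, 1]`, one column per
#' channel.
#'
#' @param path Path to a `.wav` file.
#' @return A list with `samples` (numeric matrix, samples x channels, in
#'   `[-1, 1]`), `sample_rate_hz` and `bits`.
#' @export
read_wav_file <- function(path) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  size <- file.info(path)$size
  if (is.na(size) || size < 44) stop("not a RIFF/WAVE file (too short): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop("not a RIFF/WAVE file: ", path)
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    len <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(len) == 0) break
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", len)
      fmt <- list(
        audio_format = sum(as.integer(fmt_raw[1:2]) * c(1, 256)),
        n_channels   = sum(as.integer(fmt_raw[3:4]) * c(1, 256)),
        sample_rate  = sum(as.integer(fmt_raw[5:8]) * c(1, 256, 65536, 16777216)),
        bits         = sum(as.integer(fmt_raw[15:16]) * c(1, 256))
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", len)
    } else {
      seek(con, len + len %% 2, origin = "current")
      next
    }
    if (len %% 2 == 1) seek(con, 1, origin = "current")
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV (missing fmt/data chunk): ", path)
  if (fmt$audio_format != 1L) stop("unsupported WAV encoding (only PCM supported): ", path)
  if (length(data_raw) == 0) stop("zero-length WAV data chunk: ", path)
  nch <- fmt$n_channels
  x <- switch(as.character(fmt$bits),
    "16" = {
      v <- readBin(data_raw, "integer", n = length(data_raw) / 2, size = 2,
                   signed = TRUE, endian = "little")
      v / 32768
    },
    "8" = {
      v <- readBin(data_raw, "integer", n = length(data_raw), size = 1,
                   signed = FALSE)
      (v - 128) / 128
    },
    "32" = {
      v <- readBin(data_raw, "integer", n = length(data_raw) / 4, size = 4,
                   signed = TRUE, endian = "little")
      v / 2147483648
    },
    stop("unsupported PCM bit depth: ", fmt$bits)
  )
  n <- floor(length(x) / nch)
  samples <- matrix(x[seq_len(n * nch)], ncol = nch, byrow = TRUE)
  list(samples = samples, sample_rate_hz = fmt$sample_rate, bits = fmt$bits)
}

#' Write a mono waveform as a 16-bit PCM WAV file
#'
#' @param samples Numeric vector in `[-1, 1]`; values outside are clipped.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav_file <- function(samples, sample_rate_hz, path) {
  stopifnot(is.numeric(samples), length(samples) > 0, sample_rate_hz > 0)
  x <- pmin(pmax(samples, -1), 1)
  # scale by 32768 (the read-side divisor) so a round trip only suffers the
  # half-LSB rounding error; the top code is clamped
  q <- pmin(as.integer(round(x * 32768)), 32767L)
  n_bytes <- length(q) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(sample_rate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate_hz * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(q, con, size = 2, endian = "little")
  invisible(path)
}
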