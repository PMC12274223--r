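# Minimal RIFF/WAVE reader and writer.
#
# Supports PCM 16/24/32-bit integer and IEEE float 32/64-bit, mono or
# multi-channel. Samples are exposed as doubles in [-1, 1].

#' Read a WAV file
#'
#' Parses a RIFF/WAVE container and returns the sample matrix and sample
#' rate. Integer PCM samples are rescaled to `[-1, 1]`.
#'
#' @param path Path to a WAV file.
#' @return A list with `samples` (numeric matrix, one column per channel)
#'   and `sample_rate` (Hz).
#' @keywords internal
#' @noRd
read_wav <- function(path) {
  if (!file.exists(path)) stopf("audio file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stopf("not a RIFF file: %s", path)
  readBin(con, "integer", 1, size = 4, endian = "little")  # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stopf("not a WAVE file: %s", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1, 2, signed = FALSE,
                               endian = "little"),
        n_channels   = readBin(body[3:4], "integer", 1, 2, signed = FALSE,
                               endian = "little"),
        sample_rate  = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(body[15:16], "integer", 1, 2, signed = FALSE,
                               endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size + size %% 2)  # skip (chunks are word-aligned)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stopf("malformed WAV (missing fmt/data): %s", path)
  if (fmt$audio_format == 0xFFFE) stopf("WAVE_FORMAT_EXTENSIBLE is not supported: %s", path)

  bytes <- fmt$bits %/% 8
  n_total <- length(data_raw) %/% bytes
  x <- if (fmt$audio_format == 3) {          # IEEE float
    readBin(data_raw, "double", n_total, size = bytes, endian = "little")
  } else if (fmt$audio_format == 1) {        # integer PCM
    if (fmt$bits == 24) {
      n_total <- length(data_raw) %/% 3
      b <- matrix(as.integer(data_raw[seq_len(n_total * 3)]), nrow = 3)
      v <- b[1, ] + b[2, ] * 256L + b[3, ] * 65536L
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    } else if (fmt$bits %in% c(16L, 32L)) {
      v <- readBin(data_raw, "integer", n_total, size = bytes, endian = "little")
      v / (2^(fmt$bits - 1))
    } else if (fmt$bits == 8) {
      v <- readBin(data_raw, "integer", n_total, size = 1, signed = FALSE)
      (v - 128) / 128
    } else stopf("unsupported PCM bit depth: %d", fmt$bits)
  } else stopf("unsupported WAV format code: %d", fmt$audio_format)

  nch <- max(1L, fmt$n_channels)
  n_frames <- length(x) %/% nch
  samples <- matrix(x[seq_len(n_frames * nch)], ncol = nch, byrow = TRUE)
  list(samples = samples, sample_rate = fmt$sample_rate)
}

#' Write a mono signal to a 16-bit PCM WAV file
#'
#' @param samples Numeric vector in `[-1, 1]` (values are clipped).
#' @param sample_rate Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @keywords internal
#' @noRd
write_wav <- function(samples, sample_rate, path) {
  x <- pmax(-1, pmin(1, samples))
  pcm <- as.integer(round(x * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
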