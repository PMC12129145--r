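#' Read a RIFF/WAVE file
#'
#' Minimal WAV reader supporting 16- and 24-bit integer PCM and 32-bit IEEE
#' float, any sample rate and channel count. No resampling is performed.
#'
#' @param path path to a `.wav` file.
#' @param expected_channels if not `NULL`, error unless the file has exactly
#'   this many channels.
#' @return a list with `samples` (numeric matrix, one column per channel,
#'   amplitudes in `[-1, 1]`), `sample_rate` (Hz) and `bit_depth`.
#' @export
read_wav <- function(path, expected_channels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readChar(con, 4, useBytes = TRUE), "RIFF"))
    stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(sz) == 0) break
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1, 2, signed = FALSE,
                               endian = "little"),
        n_channels   = readBin(raw[3:4], "integer", 1, 2, signed = FALSE,
                               endian = "little"),
        sample_rate  = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(raw[15:16], "integer", 1, 2, signed = FALSE,
                               endian = "little"))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      seek(con, sz, origin = "current")
    }
    if (sz %% 2 == 1) readBin(con, "raw", 1) # chunk padding byte
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV file: ", path)

  x <- if (fmt$audio_format == 3 && fmt$bits == 32) {
    readBin(data_raw, "double", length(data_raw) / 4, size = 4,
            endian = "little")
  } else if (fmt$audio_format == 1 && fmt$bits == 16) {
    readBin(data_raw, "integer", length(data_raw) / 2, size = 2,
            signed = TRUE, endian = "little") / 32768
  } else if (fmt$audio_format == 1 && fmt$bits == 24) {
    b <- as.integer(data_raw)
    n <- length(b) %/% 3
    v <- b[seq(1, by = 3, length.out = n)] +
      256 * b[seq(2, by = 3, length.out = n)] +
      65536 * b[seq(3, by = 3, length.out = n)]
    ifelse(v >= 8388608, v - 16777216, v) / 8388608
  } else {
    stop("unsupported WAV encoding (format ", fmt$audio_format, ", ",
         fmt$bits, " bits)")
  }
  if (!is.null(expected_channels) && fmt$n_channels != expected_channels)
    stop("expected ", expected_channels, " channel(s), file has ",
         fmt$n_channels)
  samples <- matrix(x, ncol = fmt$n_channels, byrow = TRUE)
  list(samples = samples, sample_rate = fmt$sample_rate, bit_depth = fmt$bits)
}

#' Write a RIFF/WAVE file
#'
#' Writes 16-bit integer PCM (default, the rendering output format) or
#' 32-bit IEEE float. Amplitudes are clamped to `[-1, 1]`.
#'
#' @param samples numeric vector (mono) or matrix (one column per channel).
#' @param sample_rate sampling rate in Hz.
#' @param path output path.
#' @param bit_depth 16 (integer PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path, bit_depth = 16) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  stopifnot(bit_depth %in% c(16, 32))
  x <- t(samples)            # interleave channels
  x <- pmin(1, pmax(-1, as.numeric(x)))
  n_ch <- ncol(samples)
  bytes_per <- bit_depth / 8
  data_size <- length(x) * bytes_per
  fmt_code <- if (bit_depth == 16) 1L else 3L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(as.integer(n_ch), con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * n_ch * bytes_per), con, size = 4,
           endian = "little")
  writeBin(as.integer(n_ch * bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bit_depth), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bit_depth == 16) {
    writeBin(as.integer(round(x * 32767)), con, size = 2, endian = "little")
  } else {
    writeBin(x, con, size = 4, endian = "little")
  }
  invisible(path)
}
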