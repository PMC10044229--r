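#' Read a mono WAV file
#'
#' Minimal RIFF/WAVE reader covering the formats this package writes:
#' uncompressed PCM (8/16/24/32 bit integer) and IEEE float32/float64,
#' single channel (multi-channel files are averaged to mono with a warning).
#' Samples are returned as dimensionless amplitudes in \[-1, 1\].
#'
#' @param path path to a .wav file
#' @return an [audio_segment()] with attributes `rate` and `samples`
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz + sz %% 2)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1, 2, signed = FALSE, endian = "little"),
        n_channels   = readBin(body[3:4], "integer", 1, 2, signed = FALSE, endian = "little"),
        sample_rate  = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(body[15:16], "integer", 1, 2, signed = FALSE, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2 == 1) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", sz + sz %% 2)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV (missing fmt/data chunk): ", path)

  bytes <- fmt$bits / 8L
  n <- length(data_raw) %/% bytes
  x <- switch(
    as.character(fmt$audio_format),
    "1" = { # integer PCM
      if (fmt$bits == 8L) {
        (as.integer(data_raw) - 128) / 127
      } else if (fmt$bits == 24L) {
        m <- matrix(as.integer(data_raw[seq_len(n * 3L)]), nrow = 3L)
        v <- m[1, ] + 256L * m[2, ] + 65536L * m[3, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        v / 8388607
      } else {
        # symmetric scale (2^(bits-1) - 1) matches the writer, so a write/
        # read round trip stays within half an LSB
        readBin(data_raw, "integer", n, bytes, signed = TRUE, endian = "little") /
          (2^(fmt$bits - 1) - 1)
      }
    },
    "3" = readBin(data_raw, "double", n, bytes, endian = "little"),
    stop("unsupported WAV audio format code: ", fmt$audio_format)
  )
  if (fmt$n_channels > 1L) {
    warning("averaging ", fmt$n_channels, " channels to mono")
    x <- colMeans(matrix(x, nrow = fmt$n_channels))
  }
  audio_segment(x, rate = fmt$sample_rate)
}

#' Write a mono WAV file
#'
#' @param segment an [audio_segment()] or numeric vector of amplitudes
#' @param path output path
#' @param rate sample rate in Hz (taken from the segment if present)
#' @param bits 16 (integer PCM) or 32 (IEEE float)
#' @return `path`, invisibly
#' @export
write_wav <- function(segment, path, rate = NULL, bits = 16L) {
  x <- as.numeric(segment)
  if (is.null(rate)) rate <- attr(segment, "rate")
  if (is.null(rate)) stop("sample rate required")
  stopifnot(bits %in% c(16L, 32L))
  rate <- as.integer(round(rate))

  if (bits == 16L) {
    fmt_code <- 1L
    x <- pmax(-1, pmin(1, x))
    payload_n <- length(x) * 2L
  } else {
    fmt_code <- 3L
    payload_n <- length(x) * 4L
  }
  block_align <- bits %/% 8L
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + payload_n), con, 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(fmt_code, con, 2L, endian = "little")
  writeBin(1L, con, 2L, endian = "little")          # mono
  writeBin(rate, con, 4L, endian = "little")
  writeBin(as.integer(rate * block_align), con, 4L, endian = "little")
  writeBin(as.integer(block_align), con, 2L, endian = "little")
  writeBin(as.integer(bits), con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(payload_n), con, 4L, endian = "little")
  if (bits == 16L) {
    writeBin(as.integer(round(x * 32767)), con, 2L, endian = "little")
  } else {
    writeBin(as.numeric(x), con, 4L, endian = "little")
  }
  invisible(path)
}
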