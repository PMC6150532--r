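#' Read a multichannel RIFF WAV file
#'
#' Minimal WAV codec used by the pipeline for on-disk audio. Supports the
#' formats the package itself writes: 16-bit integer PCM and 32-bit IEEE
#' float, any channel count, arbitrary sample rate.
#'
#' @param path path to a `.wav` file.
#' @return a list with `samples` (numeric matrix, samples x channels, float
#'   scale in \[-1, 1\] for PCM input), `sample_rate` (Hz) and `bits`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    stop_usv("'%s' is not a RIFF/WAV file", path, class = "usvdyad_format_error")
  }
  readBin(con, "integer", 1, 4, endian = "little")   # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    stop_usv("'%s' is not a WAVE file", path, class = "usvdyad_format_error")
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1, 2, endian = "little"),
        n_channels   = readBin(body[3:4], "integer", 1, 2, endian = "little"),
        sample_rate  = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(body[15:16], "integer", 1, 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size + (size %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop_usv("'%s': missing fmt or data chunk", path, class = "usvdyad_format_error")
  }
  nch <- fmt$n_channels
  if (fmt$audio_format == 3L && fmt$bits == 32L) {
    x <- readBin(data_raw, "double", length(data_raw) / 4L, size = 4,
                 endian = "little")
  } else if (fmt$audio_format == 1L && fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", length(data_raw) / 2L, size = 2,
                 signed = TRUE, endian = "little") / 32768
  } else {
    stop_usv("unsupported WAV encoding (format %d, %d bits)",
             fmt$audio_format, fmt$bits, class = "usvdyad_format_error")
  }
  samples <- matrix(x, ncol = nch, byrow = TRUE)
  list(samples = samples, sample_rate = fmt$sample_rate, bits = fmt$bits)
}

#' Inspect a WAV header without reading the payload
#'
#' @param path path to a `.wav` file.
#' @return list with `n_channels`, `sample_rate`, `bits`, `n_samples`
#'   (per channel).
#' @export
wav_info <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readChar(con, 4, useBytes = TRUE), "RIFF")) {
    stop_usv("'%s' is not a RIFF/WAV file", path, class = "usvdyad_format_error")
  }
  readBin(con, "integer", 1, 4, endian = "little")
  readChar(con, 4, useBytes = TRUE)
  fmt <- NULL
  n_bytes <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        n_channels  = readBin(body[3:4], "integer", 1, 2, endian = "little"),
        sample_rate = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits        = readBin(body[15:16], "integer", 1, 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      n_bytes <- size
      break
    } else {
      readBin(con, "raw", size + (size %% 2L))
    }
  }
  if (is.null(fmt) || is.null(n_bytes)) {
    stop_usv("'%s': missing fmt or data chunk", path, class = "usvdyad_format_error")
  }
  list(n_channels = fmt$n_channels, sample_rate = fmt$sample_rate,
       bits = fmt$bits,
       n_samples = n_bytes %/% (fmt$n_channels * fmt$bits %/% 8L))
}

#' Write a multichannel WAV file
#'
#' @param samples numeric matrix (samples x channels) or vector.
#' @param path output path.
#' @param sample_rate sampling rate in Hz.
#' @param bits 32 (IEEE float, lossless for analysis, the default) or 16
#'   (integer PCM; values are clipped to \[-1, 1\]).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate, bits = 32L) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  nch <- ncol(samples)
  interleaved <- as.numeric(t(samples))
  if (bits == 32L) {
    payload <- writeBin(interleaved, raw(), size = 4, endian = "little")
    fmt_code <- 3L
  } else if (bits == 16L) {
    q <- pmin(pmax(interleaved, -1), 32767 / 32768)
    payload <- writeBin(as.integer(round(q * 32768)), raw(), size = 2,
                        endian = "little")
    fmt_code <- 1L
  } else {
    stop_usv("bits must be 16 or 32", class = "usvdyad_format_error")
  }
  bytes_per <- bits %/% 8L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + length(payload)), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(as.integer(nch), con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * nch * bytes_per), con, size = 4,
           endian = "little")
  writeBin(as.integer(nch * bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(length(payload)), con, size = 4, endian = "little")
  writeBin(payload, con)
  invisible(path)
}
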