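# Minimal RIFF/WAVE I/O for mono recordings.
#
# Supports the two encodings the pipeline meets: IEEE float32 (the
# acquisition format, 44.1 kHz) and PCM16 (the analysis format after
# downsampling).  Kept deliberately small; only mono files are handled.

#' Write a mono waveform to a WAV file
#'
#' @param samples numeric vector in \[-1, 1\].
#' @param path output file path.
#' @param rate sampling rate in Hz.
#' @param bit_depth `"float32"` (IEEE float) or `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, rate, bit_depth = c("float32", "pcm16")) {
  bit_depth <- match.arg(bit_depth)
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(samples)
  if (bit_depth == "float32") {
    fmt <- 3L; bits <- 32L; data_bytes <- 4L * n
  } else {
    fmt <- 1L; bits <- 16L; data_bytes <- 2L * n
  }
  block <- bits %/% 8L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * block), con, size = 4, endian = "little")
  writeBin(block, con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  if (bit_depth == "float32") {
    writeBin(as.numeric(samples), con, size = 4, endian = "little")
  } else {
    q <- as.integer(pmax(-32768, pmin(32767, round(samples * 32767))))
    writeBin(q, con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file
#'
#' @param path WAV file path.
#' @return A `waveform` object: list with `samples`, `rate`, `bit_depth`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stopf("not a RIFF file: %s", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  if (!identical(readChar(con, 4), "WAVE")) stopf("not a WAVE file: %s", path)
  fmt <- NULL; bits <- NULL; rate <- NULL; channels <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stopf("no data chunk in %s", path)
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 1, size = 2, endian = "little")
      channels <- readBin(con, "integer", 1, size = 2, endian = "little")
      rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (sz > 16) readBin(con, "raw", sz - 16)
    } else if (id == "data") {
      if (is.null(fmt)) stopf("data chunk before fmt in %s", path)
      if (channels != 1L) stopf("only mono WAV supported (%s)", path)
      if (fmt == 3L && bits == 32L) {
        x <- readBin(con, "numeric", sz / 4, size = 4, endian = "little")
        bd <- "float32"
      } else if (fmt == 1L && bits == 16L) {
        x <- readBin(con, "integer", sz / 2, size = 2, signed = TRUE,
                     endian = "little") / 32767
        bd <- "pcm16"
      } else stopf("unsupported WAV encoding (fmt=%d, bits=%d)", fmt, bits)
      return(waveform(x, rate, bd))
    } else {
      readBin(con, "raw", sz + (sz %% 2))
    }
  }
}

#' Construct a waveform object
#'
#' @param samples numeric vector of samples in \[-1, 1\].
#' @param rate sampling rate in Hz (> 0).
#' @param bit_depth encoding tag.
#' @return A `waveform` list object.
#' @export
waveform <- function(samples, rate, bit_depth = "float32") {
  stopifnot(rate > 0)
  structure(list(samples = as.numeric(samples), rate = as.numeric(rate),
                 bit_depth = bit_depth), class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %.2f s @ %g Hz (%s)\n",
              length(x$samples) / x$rate, x$rate, x$bit_depth))
  invisible(x)
}
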