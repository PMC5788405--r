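#' Read a mono WAV file
#'
#' Minimal RIFF/WAVE reader supporting uncompressed PCM 16-bit and IEEE
#' float32 mono files. If the file's rate differs from `sample_rate`, the
#' waveform is resampled (polyphase, [signal::resample()]) with a warning.
#'
#' @param path Path to a `.wav` file.
#' @param sample_rate Target working rate in Hz, or `NULL` to keep the
#'   file's native rate. Analyses in this package default to 24 kHz.
#' @return Numeric vector of samples in `[-1, 1]` with attributes
#'   `sample_rate` (Hz).
#' @export
read_wav <- function(path, sample_rate = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = sum(as.integer(fmt_raw[1:2]) * c(1, 256)),
        n_channels   = sum(as.integer(fmt_raw[3:4]) * c(1, 256)),
        sample_rate  = sum(as.integer(fmt_raw[5:8]) * 256^(0:3)),
        bits         = sum(as.integer(fmt_raw[15:16]) * c(1, 256))
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV file: ", path)
  if (fmt$n_channels != 1L) stop("mono required")
  x <- if (fmt$audio_format == 1L && fmt$bits == 16L) {
    readBin(data_raw, "integer", length(data_raw) / 2, 2,
            signed = TRUE, endian = "little") / 32768
  } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
    readBin(data_raw, "double", length(data_raw) / 4, 4, endian = "little")
  } else {
    stop("unsupported WAV encoding (need PCM16 or float32)")
  }
  fs <- fmt$sample_rate
  if (!is.null(sample_rate) && fs != sample_rate) {
    warning(sprintf("resampling %s from %d Hz to %d Hz", basename(path),
                    fs, as.integer(sample_rate)))
    x <- resample_wave(x, fs, sample_rate)
    fs <- sample_rate
  }
  structure(x, sample_rate = fs)
}

#' Write a mono WAV file
#'
#' @param wave Numeric samples, nominally in `[-1, 1]`.
#' @param path Output path.
#' @param sample_rate Sample rate in Hz.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path, sample_rate, bits = 16L) {
  stopifnot(is.numeric(wave), bits %in% c(16L, 32L))
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(wave)
  bytes <- as.integer(bits / 8)
  fmt_code <- if (bits == 16L) 1L else 3L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + n * bytes), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(fmt_code, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(as.integer(sample_rate), con, 4, endian = "little")
  writeBin(as.integer(sample_rate * bytes), con, 4, endian = "little")
  writeBin(bytes, con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n * bytes), con, 4, endian = "little")
  if (bits == 16L) {
    q <- as.integer(round(pmax(pmin(wave, 1), -1) * 32767))
    writeBin(q, con, 2, endian = "little")
  } else {
    writeBin(as.double(wave), con, 4, endian = "little")
  }
  invisible(path)
}

#' Resample a waveform
#'
#' Rational-factor polyphase resampling via [signal::resample()].
#'
#' @param wave Numeric samples.
#' @param from,to Source and target rates in Hz.
#' @return Resampled numeric vector.
#' @export
resample_wave <- function(wave, from, to) {
  if (from == to) return(wave)
  r <- .rational(to / from)
  as.numeric(signal::resample(wave, p = r[1], q = r[2]))
}

.rational <- function(x, tol = 1e-9, max_den = 100000L) {
  # continued-fraction rational approximation
  p0 <- 0L; q0 <- 1L; p1 <- 1L; q1 <- 0L; y <- x
  repeat {
    a <- floor(y)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(x - p1 / q1) < tol * x) break
    if (y == a) break
    y <- 1 / (y - a)
  }
  c(p1, q1)
}
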