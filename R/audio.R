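#' Construct an audio signal
#'
#' The basic container passed between all pipeline stages: a mono amplitude
#' sequence plus its sampling rate. Amplitudes are expected on a peak scale
#' (max absolute value 1 after [read_wav()] with `normalize = TRUE`), which
#' keeps the fixed feature thresholds of [pipeline_config()] portable across
#' recordings.
#'
#' @param samples numeric vector of amplitudes (dimensionless).
#' @param rate sampling rate in Hz (positive scalar).
#' @return an object of class `audio_signal` with fields `samples` and `rate`.
#' @examples
#' s <- audio_signal(sin(2 * pi * 220 * seq(0, 0.1, by = 1 / 8000)), 8000)
#' duration(s)
#' @export
audio_signal <- function(samples, rate) {
  if (!is.numeric(samples) || length(samples) < 1L)
    stop("'samples' must be a non-empty numeric vector")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("'rate' must be a single positive number")
  if (any(!is.finite(samples)))
    stop("'samples' contains non-finite values")
  structure(list(samples = as.numeric(samples), rate = as.numeric(rate)),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal: %d samples @ %g Hz (%.3f s), peak %.3f>\n",
              length(x$samples), x$rate, duration(x), max(abs(x$samples))))
  invisible(x)
}

#' Signal duration in seconds
#' @param signal an [audio_signal()].
#' @return duration in seconds.
#' @export
duration <- function(signal) length(signal$samples) / signal$rate

#' Peak-normalize a signal
#'
#' Scales the waveform so that max |amplitude| equals `peak`. An all-zero
#' signal is returned unchanged.
#'
#' @param signal an [audio_signal()].
#' @param peak target peak amplitude.
#' @export
peak_normalize <- function(signal, peak = 1) {
  m <- max(abs(signal$samples))
  if (m > 0) signal$samples <- signal$samples / m * peak
  signal
}

#' Resample a signal to a new rate
#'
#' Rational-factor polyphase resampling (via \pkg{signal}). A no-op when the
#' rates already agree. All feature thresholds in this package are calibrated
#' at 44100 Hz, so the pipeline resamples every input to the configured rate
#' before feature extraction.
#'
#' @param signal an [audio_signal()].
#' @param rate target sampling rate in Hz.
#' @export
resample_signal <- function(signal, rate) {
  if (signal$rate == rate) return(signal)
  frac <- .rat_approx(rate / signal$rate)
  y <- signal::resample(signal$samples, frac[1], frac[2])
  n_target <- round(length(signal$samples) * rate / signal$rate)
  if (length(y) > n_target) y <- y[seq_len(n_target)]
  if (length(y) < n_target) y <- c(y, numeric(n_target - length(y)))
  audio_signal(y, rate)
}

# small continued-fraction rational approximation p/q of x
.rat_approx <- function(x, tol = 1e-9, max_q = 10000L) {
  p0 <- 0L; q0 <- 1L; p1 <- 1L; q1 <- 0L; r <- x
  repeat {
    a <- floor(r)
    p <- a * p1 + p0; q <- a * q1 + q0
    if (q > max_q || abs(p / q - x) < tol) return(c(round(p), round(q)))
    p0 <- p1; q0 <- q1; p1 <- p; q1 <- q
    if (abs(r - a) < 1e-15) return(c(round(p), round(q)))
    r <- 1 / (r - a)
  }
}

#' Extract a time slice of a signal
#'
#' Half-open interval `[from_s, to_s)`, clamped to the signal extent.
#'
#' @param signal an [audio_signal()].
#' @param from_s,to_s slice bounds in seconds.
#' @export
slice_signal <- function(signal, from_s, to_s) {
  n <- length(signal$samples)
  i0 <- max(1L, floor(from_s * signal$rate) + 1L)
  i1 <- min(n, ceiling(to_s * signal$rate))
  if (i1 < i0) stop("empty slice: [", from_s, ", ", to_s, ")")
  audio_signal(signal$samples[i0:i1], signal$rate)
}

#' Read a WAV file
#'
#' Minimal RIFF/WAVE reader for uncompressed PCM (8/16/24/32-bit integer) and
#' IEEE float (32/64-bit) files. Multi-channel input is averaged to mono;
#' the result is optionally resampled and peak-normalized, which is the
#' canonical load path of the segmentation pipeline.
#'
#' @param path WAV file path.
#' @param rate if non-`NULL`, resample to this rate (Hz).
#' @param normalize peak-normalize to max |amplitude| = 1 (default `TRUE`).
#' @return an [audio_signal()].
#' @export
read_wav <- function(path, rate = NULL, normalize = TRUE) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
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
        audio_format = .le_uint(fmt_raw[1:2]),
        channels     = .le_uint(fmt_raw[3:4]),
        sample_rate  = .le_uint(fmt_raw[5:8]),
        bits         = .le_uint(fmt_raw[15:16]))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("malformed WAV (missing fmt/data chunk): ", path)
  x <- .decode_pcm(data_raw, fmt)
  if (length(x) == 0) stop("WAV file contains no samples: ", path)
  if (fmt$channels > 1L) {
    x <- rowMeans(matrix(x, ncol = fmt$channels, byrow = TRUE))
    message("averaged ", fmt$channels, " channels to mono")
  }
  sig <- audio_signal(x, fmt$sample_rate)
  if (!is.null(rate)) sig <- resample_signal(sig, rate)
  if (normalize) sig <- peak_normalize(sig)
  sig
}

.le_uint <- function(bytes) sum(as.integer(bytes) * 256^(seq_along(bytes) - 1))

.decode_pcm <- function(raw, fmt) {
  if (fmt$audio_format == 3) {          # IEEE float
    return(readBin(raw, "double", length(raw) / (fmt$bits / 8),
                   size = fmt$bits / 8, endian = "little"))
  }
  if (fmt$audio_format != 1) stop("unsupported WAV encoding: ", fmt$audio_format)
  bytes <- fmt$bits / 8
  n <- length(raw) %/% bytes
  if (fmt$bits == 8) {
    (as.integer(raw[seq_len(n)]) - 128) / 128
  } else if (fmt$bits %in% c(16, 32)) {
    readBin(raw, "integer", n, size = bytes, signed = TRUE,
            endian = "little") / 2^(fmt$bits - 1)
  } else if (fmt$bits == 24) {
    m <- matrix(as.integer(raw[seq_len(3 * n)]), nrow = 3)
    v <- m[1, ] + m[2, ] * 256 + m[3, ] * 65536
    v <- ifelse(v >= 2^23, v - 2^24, v)
    v / 2^23
  } else stop("unsupported PCM bit depth: ", fmt$bits)
}

#' Write a WAV file
#'
#' Writes mono PCM WAV (16 or 24 bit). Samples are clipped to \[-1, 1\].
#' The file is written atomically (temporary file then rename).
#'
#' @param signal an [audio_signal()].
#' @param path output path.
#' @param bits 16 (default) or 24.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path, bits = 16) {
  if (!bits %in% c(16, 24)) stop("'bits' must be 16 or 24")
  x <- pmax(-1, pmin(1, signal$samples))
  n <- length(x)
  bytes <- bits / 8
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".wav.tmp")
  con <- file(tmp, "wb")
  ok <- FALSE
  on.exit({ close(con); if (ok) file.rename(tmp, path) else unlink(tmp) })
  data_size <- n * bytes
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, size = 4, endian = "little")
  writeBin(as.integer(1), con, size = 2, endian = "little")   # PCM
  writeBin(as.integer(1), con, size = 2, endian = "little")   # mono
  writeBin(as.integer(signal$rate), con, size = 4, endian = "little")
  writeBin(as.integer(signal$rate * bytes), con, size = 4, endian = "little")
  writeBin(as.integer(bytes), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  q <- round(x * (2^(bits - 1) - 1))
  if (bits == 16) {
    writeBin(as.integer(q), con, size = 2, endian = "little")
  } else {
    v <- ifelse(q < 0, q + 2^24, q)
    m <- rbind(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256)
    writeBin(as.raw(m), con)
  }
  ok <- TRUE
  invisible(path)
}
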