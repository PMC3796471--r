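#' Construct a waveform object
#'
#' A waveform is sampled mono audio: a numeric vector of dimensionless
#' amplitudes together with a sample rate. Amplitudes are expected to stay in
#' \[-1, 1\] for digital (full-scale) audio; pressure-unit waveforms (Pa) used
#' by the propagation simulator may exceed that range.
#'
#' @param samples numeric vector of sample amplitudes.
#' @param sample_rate sampling rate in Hz (default 44100).
#' @return an object of class \code{"waveform"}.
#' @export
waveform <- function(samples, sample_rate = 44100) {
  stopifnot(is.numeric(samples), length(samples) > 0L,
            is.numeric(sample_rate), sample_rate > 0)
  structure(list(samples = as.numeric(samples),
                 sample_rate = as.numeric(sample_rate)),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %d samples @ %g Hz (%.3f s), peak %.4f>\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate,
              max(abs(x$samples))))
  invisible(x)
}

#' Duration of a waveform in seconds
#' @param wave a \code{waveform}.
#' @return duration in seconds.
#' @export
wave_duration <- function(wave) {
  stopifnot(inherits(wave, "waveform"))
  length(wave$samples) / wave$sample_rate
}

#' Concatenate waveforms
#'
#' All parts must share a sample rate.
#'
#' @param ... waveform objects.
#' @return a single \code{waveform}.
#' @export
wave_concat <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) && !inherits(parts[[1]], "waveform"))
    parts <- parts[[1]]
  stopifnot(length(parts) > 0L)
  sr <- unique(vapply(parts, function(w) w$sample_rate, numeric(1)))
  if (length(sr) != 1L) stop("all waveforms must share a sample rate")
  waveform(unlist(lapply(parts, function(w) w$samples), use.names = FALSE), sr)
}

#' Silence of a given duration
#' @param duration seconds.
#' @param sample_rate Hz.
#' @return a \code{waveform} of zeros.
#' @export
silence <- function(duration, sample_rate = 44100) {
  waveform(numeric(max(1L, round(duration * sample_rate))), sample_rate)
}

# RMS of a sample vector (optionally trimming `trim` seconds off each edge,
# to exclude onset/offset ramps from level measurements).
sample_rms <- function(x, sample_rate = NULL, trim = 0) {
  if (trim > 0) {
    stopifnot(!is.null(sample_rate))
    k <- round(trim * sample_rate)
    if (2L * k < length(x)) x <- x[(k + 1L):(length(x) - k)]
  }
  sqrt(mean(x^2))
}

#' Write a waveform to a mono 16-bit PCM WAV file
#'
#' Samples are clipped to \[-1, 1\] and quantized to 16-bit integers.
#'
#' @param wave a \code{waveform} with samples in \[-1, 1\].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
wav_write <- function(wave, path) {
  stopifnot(inherits(wave, "waveform"))
  x <- pmax(-1, pmin(1, wave$samples))
  pcm <- as.integer(round(x * 32767))
  n <- length(pcm)
  sr <- as.integer(round(wave$sample_rate))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + 2L * n), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")      # PCM
  writeBin(1L, con, size = 2, endian = "little")      # mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(as.integer(sr * 2L), con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")      # block align
  writeBin(16L, con, size = 2, endian = "little")     # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2L * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' Minimal reader for the files this package writes (PCM 16-bit, one channel).
#'
#' @param path WAV file path.
#' @return a \code{waveform} with samples scaled to \[-1, 1\].
#' @export
wav_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave_tag <- readChar(con, 4)
  if (!identical(wave_tag, "WAVE")) stop("not a WAVE file: ", path)
  sr <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    tag <- readChar(con, 4)
    if (length(tag) == 0L || nchar(tag) < 4L) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(tag, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      channels <- fmt[2]
      sr <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      extra <- size - 16L
      if (extra > 0L) invisible(readBin(con, "raw", extra))
    } else if (identical(tag, "data")) {
      samples <- readBin(con, "integer", size / 2L, size = 2,
                         signed = TRUE, endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  if (!identical(channels, 1L) || !identical(bits, 16L))
    stop("only mono 16-bit PCM WAV is supported")
  waveform(samples / 32767, sr)
}
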