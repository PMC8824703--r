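#' Mono audio signal
#'
#' A lightweight container for a sampled mono waveform: a numeric vector
#' of dimensionless amplitudes (nominal range \[-1, 1\]) plus its sample
#' rate. All DSP in the package operates on this class.
#'
#' @param samples numeric vector of finite amplitudes.
#' @param sample_rate sample rate in Hz (> 0).
#' @param id optional identity label (e.g. a sentence id); used by
#'   stimulus constructors to enforce distinct-sentence constraints.
#' @return an object of class `audio_signal`.
#' @export
audio_signal <- function(samples, sample_rate, id = NULL) {
  samples <- as.numeric(samples)
  if (any(!is.finite(samples))) stop_domain("samples must be finite")
  if (!(is.numeric(sample_rate) && sample_rate > 0))
    stop_domain("sample_rate must be > 0")
  structure(list(samples = samples, sample_rate = sample_rate, id = id),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("audio_signal: %d samples @ %g Hz (%.3f s)%s, peak %.3f, rms %.4f\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate,
              if (is.null(x$id)) "" else paste0(", id=", x$id),
              if (length(x$samples)) max(abs(x$samples)) else NA_real_,
              rms(x$samples)))
  invisible(x)
}

#' @export
length.audio_signal <- function(x) length(x$samples)

#' Duration of an audio signal in seconds
#' @param x an [audio_signal()].
#' @return seconds.
#' @export
duration <- function(x) length(x$samples) / x$sample_rate

#' Peak-normalize a signal
#'
#' Scales so the maximum absolute sample equals `peak` (default 0.9,
#' headroom against clipping when writing 16-bit PCM). Silence is
#' returned unchanged.
#'
#' @param x an [audio_signal()].
#' @param peak target peak amplitude.
#' @return an [audio_signal()].
#' @export
normalize_peak <- function(x, peak = 0.9) {
  m <- max(abs(x$samples))
  if (m == 0) return(x)
  audio_signal(x$samples * (peak / m), x$sample_rate, x$id)
}

# Scale to a target RMS level.
normalize_rms <- function(x, rms_ref) {
  r <- rms(x$samples)
  if (r == 0) stop_domain("cannot RMS-normalize silence")
  audio_signal(x$samples * (rms_ref / r), x$sample_rate, x$id)
}

# Loop or truncate a waveform to n samples.
fit_length <- function(samples, n) {
  if (length(samples) >= n) return(samples[seq_len(n)])
  rep_len(samples, n)
}

#' Write a mono 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE writer (no R audio package is required). Samples
#' are clipped to \[-1, 1\] and quantized to 16 bits.
#'
#' @param x an [audio_signal()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path) {
  s <- pmin(pmax(x$samples, -1), 1)
  pcm <- as.integer(round(s * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")     # PCM
  writeBin(1L, con, size = 2, endian = "little")     # mono
  writeBin(as.integer(x$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(x$sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")     # block align
  writeBin(16L, con, size = 2, endian = "little")    # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' @param path WAV file written by [write_wav()] or any mono PCM16 RIFF
#'   file.
#' @return an [audio_signal()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop_domain("not a RIFF file: %s", path)
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop_domain("not a WAVE file: %s", path)
  sample_rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop_domain("no data chunk in %s", path)
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1 || fmt[2] != 1)
        stop_domain("only mono PCM supported (%s)", path)
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, raw(), n = sz - 8)
    } else if (id == "data") {
      pcm <- readBin(con, integer(), n = sz / 2, size = 2, signed = TRUE,
                     endian = "little")
      return(audio_signal(pcm / 32767, sample_rate))
    } else {
      readBin(con, raw(), n = sz)
    }
  }
}
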