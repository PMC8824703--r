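#' Synthesize a deterministic speech-like test signal
#'
#' A stand-in for recorded sentences: a harmonic glottal-like source
#' (f0 near 110 Hz with slow random drift) shaped by three time-varying
#' formant resonators whose targets change syllable by syllable, under
#' syllabic (3–5 Hz) amplitude modulation. The output is bit-for-bit
#' reproducible for a given seed. It emulates the spectro-temporal
#' structure a vocoder cares about (harmonicity, formant peaks, slow
#' envelope), not phonetic content.
#'
#' @param dur duration in seconds, in `[1, 5]`.
#' @param seed integer seed.
#' @param sample_rate sample rate in Hz.
#' @param id optional identity label passed to [audio_signal()].
#' @return an [audio_signal()], peak-normalized to 0.9.
#' @examples
#' s <- synth_speechlike(1.5, seed = 7)
#' @export
synth_speechlike <- function(dur, seed, sample_rate = 22050, id = NULL) {
  if (!(dur >= 1 && dur <= 5)) stop_domain(
    "duration must lie in [1, 5] s (got %g)", dur)
  with_seed(derive_seed(seed, "speechlike"), {
    n <- round(dur * sample_rate)
    t <- (seq_len(n) - 1) / sample_rate
    # f0 contour: 110 Hz with slow sinusoidal drift (random phase/depth)
    f0 <- 110 * (1 + 0.08 * sin(2 * pi * stats::runif(1, 0.3, 0.8) * t +
                                  stats::runif(1, 0, 2 * pi)))
    phase <- 2 * pi * cumsum(f0) / sample_rate
    # harmonic source with gentle spectral tilt (-6 dB/octave-ish)
    src <- numeric(n)
    n_harm <- floor((sample_rate / 2 - 500) / 110)
    for (h in seq_len(min(n_harm, 40))) src <- src + sin(h * phase) / h
    # syllables: 3-5 Hz rate, per-syllable formant targets
    syl_rate <- stats::runif(1, 3, 5)
    n_syl <- max(1, round(dur * syl_rate))
    bounds <- round(seq(1, n + 1, length.out = n_syl + 1))
    out <- numeric(n)
    for (s in seq_len(n_syl)) {
      idx <- bounds[s]:(bounds[s + 1] - 1)
      seg <- src[idx]
      f_targets <- c(stats::runif(1, 300, 800),
                     stats::runif(1, 900, 2200),
                     stats::runif(1, 2300, 3200))
      shaped <- numeric(length(seg))
      for (fc in f_targets) {
        r <- exp(-pi * 80 / sample_rate) # ~80 Hz formant bandwidth
        a1 <- -2 * r * cos(2 * pi * fc / sample_rate)
        a2 <- r^2
        g <- 1 - r # keep resonator gains comparable
        shaped <- shaped +
          as.numeric(signal::filter(g, c(1, a1, a2), seg))
      }
      # raised-cosine syllable envelope
      env <- 0.1 + 0.9 * sin(pi * seq_along(seg) / length(seg))^2
      out[idx] <- shaped * env
    }
    normalize_peak(audio_signal(out, sample_rate, id), 0.9)
  })
}
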