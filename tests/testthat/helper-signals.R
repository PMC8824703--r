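# Small signal fixtures built in code.

make_tone <- function(freq, dur = 1, fs = 22050, amp = 0.5, am_freq = 0,
                      am_depth = 0) {
  t <- (seq_len(round(dur * fs)) - 1) / fs
  env <- 1 + am_depth * sin(2 * pi * am_freq * t)
  audio_signal(amp * env * sin(2 * pi * freq * t), fs)
}

silence <- function(dur = 0.5, fs = 22050) {
  audio_signal(numeric(round(dur * fs)), fs)
}

# fraction of spectral energy inside [f_lo, f_hi]
band_energy_fraction <- function(x, f_lo, f_hi) {
  s <- if (inherits(x, "audio_signal")) x$samples else x
  fs <- if (inherits(x, "audio_signal")) x$sample_rate else 22050
  p <- Mod(stats::fft(s))^2
  n <- length(p)
  f <- (seq_len(n) - 1) * fs / n
  half <- f <= fs / 2
  sum(p[half & f >= f_lo & f <= f_hi]) / sum(p[half])
}

# peak normalized cross-correlation between two waveforms
ncc_peak <- function(a, b) {
  sa <- if (inherits(a, "audio_signal")) a$samples else a
  sb <- if (inherits(b, "audio_signal")) b$samples else b
  n <- min(length(sa), length(sb))
  sa <- sa[1:n] - mean(sa[1:n]); sb <- sb[1:n] - mean(sb[1:n])
  cc <- stats::ccf(sa, sb, lag.max = round(n / 4), plot = FALSE)
  max(abs(cc$acf))
}

# two-sentence fixture pair at a given seed
sentence_pair <- function(seed = 1, dur = 1) {
  list(a = synth_speechlike(dur, seed = seed, id = paste0("sent_a", seed)),
       b = synth_speechlike(dur, seed = seed + 1000,
                            id = paste0("sent_b", seed)))
}
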