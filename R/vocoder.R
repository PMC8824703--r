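#' Sine-vocoder configuration
#'
#' Bundles the filterbank with the envelope-extraction settings and the
#' synthesis options. Envelope extraction is half-wave rectification
#' followed by a Butterworth lowpass (default fourth order at 30 Hz).
#' `flip = TRUE` performs spectral inversion: band b's envelope drives
#' the mirror band `n_bands + 1 - b`, which renders vocoded speech
#' unintelligible while preserving its complexity.
#'
#' @param filterbank a [make_filterbank()] object.
#' @param env_cutoff envelope lowpass cutoff in Hz (default 30; must lie
#'   below the lowest band centre).
#' @param env_order envelope lowpass order (default 4).
#' @param flip logical; spectral inversion on/off.
#' @param rms_match logical; restore each synthesized band to its
#'   analysis-band RMS (default TRUE).
#' @return an object of class `vocoder_config`.
#' @export
vocoder_config <- function(filterbank, env_cutoff = 30, env_order = 4,
                           flip = FALSE, rms_match = TRUE) {
  if (!inherits(filterbank, "filterbank")) stop_domain(
    "filterbank must be a make_filterbank() object")
  if (!(env_cutoff < min(filterbank$centers))) stop_domain(
    "env_cutoff (%g Hz) must lie below the lowest band centre (%g Hz)",
    env_cutoff, min(filterbank$centers))
  if (!(env_order >= 1)) stop_domain("env_order must be >= 1")
  env_filter <- butter_lowpass(env_order, env_cutoff, filterbank$sample_rate)
  structure(list(filterbank = filterbank, env_cutoff = env_cutoff,
                 env_order = env_order, flip = isTRUE(flip),
                 rms_match = isTRUE(rms_match), env_filter = env_filter),
            class = "vocoder_config")
}

#' @export
print.vocoder_config <- function(x, ...) {
  cat(sprintf(
    "Sine-vocoder config: %d bands, envelope LP order %d @ %g Hz, flip=%s, rms_match=%s\n",
    x$filterbank$n_bands, x$env_order, x$env_cutoff, x$flip, x$rms_match))
  invisible(x)
}

#' Extract the amplitude envelope of a band signal
#'
#' Half-wave rectification followed by the config's Butterworth lowpass.
#' For a constant-amplitude tone the envelope settles near
#' amplitude / pi (the mean of a half-wave-rectified sinusoid).
#'
#' @param band an [audio_signal()] (normally a bandpass-filtered band).
#' @param cfg a [vocoder_config()].
#' @return an [audio_signal()] envelope.
#' @export
extract_envelope <- function(band, cfg) {
  if (band$sample_rate != cfg$filterbank$sample_rate) stop_domain(
    "sample rate mismatch: signal %g Hz, vocoder %g Hz",
    band$sample_rate, cfg$filterbank$sample_rate)
  rect <- pmax(band$samples, 0)
  audio_signal(sos_filter(cfg$env_filter, rect), band$sample_rate)
}

#' Sine-vocode a speech signal
#'
#' Analysis: the input is split by the config's filterbank and each
#' band's amplitude envelope extracted. Synthesis: each envelope
#' multiplies a zero-phase sine carrier at a band centre and the product
#' is refiltered by that band's bandpass; the band is then rescaled to
#' the analysis band's RMS and all bands are summed. With
#' `cfg$flip = TRUE` band b's envelope is synthesized in mirror band
#' `n_bands + 1 - b` (carrier and bandpass of the destination band).
#'
#' @param speech an [audio_signal()] at the filterbank's sample rate.
#' @param cfg a [vocoder_config()].
#' @return an [audio_signal()] of the same duration. Attributes
#'   `band_rms_analysis` and `band_rms_synth` record, per source band,
#'   the analysis-band RMS and the RMS of the matched synthesized band
#'   before summation (equal whenever the analysis RMS is non-zero and
#'   `rms_match` is on).
#' @export
vocode <- function(speech, cfg) {
  fb <- cfg$filterbank
  if (speech$sample_rate != fb$sample_rate) stop_domain(
    "sample rate mismatch: signal %g Hz, filterbank %g Hz",
    speech$sample_rate, fb$sample_rate)
  n <- length(speech$samples)
  if (n == 0) stop_domain("empty input signal")
  t <- (seq_len(n) - 1) / fb$sample_rate
  out <- numeric(n)
  rms_an <- rms_sy <- numeric(fb$n_bands)
  for (b in seq_len(fb$n_bands)) {
    analysis <- sos_filter(fb$filters[[b]], speech$samples)
    rms_a <- rms(analysis)
    rms_an[b] <- rms_a
    if (rms_a == 0) next # silent band synthesizes silence
    env <- sos_filter(cfg$env_filter, pmax(analysis, 0))
    dest <- if (cfg$flip) fb$n_bands + 1 - b else b
    carrier <- sin(2 * pi * fb$centers[dest] * t)
    synth <- sos_filter(fb$filters[[dest]], env * carrier)
    if (cfg$rms_match) {
      rms_s <- rms(synth)
      if (rms_s > 0) synth <- synth * (rms_a / rms_s)
    }
    rms_sy[b] <- rms(synth)
    out <- out + synth
  }
  out <- audio_signal(out, fb$sample_rate, speech$id)
  attr(out, "band_rms_analysis") <- rms_an
  attr(out, "band_rms_synth") <- rms_sy
  out
}

#' Mix a target into a masker at a nominal SNR
#'
#' The target is scaled by `g = 10^(snr_db/20) * RMS(masker)/RMS(target)`
#' so the component RMS ratio equals the nominal SNR, the two are
#' summed, and the mixture is normalized to the reference RMS level (so
#' stimuli across conditions share overall intensity). The masker is
#' looped or truncated to the target's length first.
#'
#' @param target,masker [audio_signal()]s at equal sample rates.
#' @param snr_db nominal signal-to-noise ratio in dB.
#' @param rms_ref reference RMS of the normalized mixture.
#' @return an [audio_signal()]; attributes `gain` (target gain applied)
#'   and `snr_achieved_db` record the realized mix.
#' @export
mix_at_snr <- function(target, masker, snr_db, rms_ref = 0.05) {
  if (target$sample_rate != masker$sample_rate) stop_domain(
    "sample rate mismatch between target and masker")
  m <- fit_length(masker$samples, length(target$samples))
  rt <- rms(target$samples); rm_ <- rms(m)
  if (rt == 0) stop_domain("target has zero RMS")
  if (rm_ == 0) stop_domain("masker has zero RMS")
  g <- 10^(snr_db / 20) * rm_ / rt
  mix <- normalize_rms(audio_signal(g * target$samples + m,
                                    target$sample_rate), rms_ref)
  attr(mix, "gain") <- g
  attr(mix, "snr_achieved_db") <- 20 * log10(rms(g * target$samples) / rm_)
  mix
}

#' Build one two-sentence vocoded trial
#'
#' An *intelligible* trial mixes the plain sine-vocoded rendering of
#' `sentence_a` with a frequency-flipped (unintelligible) rendering of
#' `sentence_b`, which acts as a competing noise source, at the
#' condition's SNR. An *unintelligible* trial flips both components and
#' mixes them at the same SNR, giving a control with equivalent
#' complexity and overall intensity. Both kinds are normalized to the
#' same reference RMS.
#'
#' @param kind `"intelligible"` or `"unintelligible"`.
#' @param sentence_a,sentence_b distinct [audio_signal()] sentences
#'   (distinctness is checked via their `id`s, or sample identity when
#'   ids are absent).
#' @param cond a [stimulus_condition()].
#' @param cfg a [vocoder_config()] (its `flip` field is ignored; the
#'   trial builder sets flipping per component).
#' @param rms_ref reference RMS of the finished trial.
#' @return an [audio_signal()].
#' @export
make_trial <- function(kind = c("intelligible", "unintelligible"),
                       sentence_a, sentence_b, cond, cfg, rms_ref = 0.05) {
  kind <- match.arg(kind)
  same <- if (!is.null(sentence_a$id) && !is.null(sentence_b$id)) {
    identical(sentence_a$id, sentence_b$id)
  } else {
    identical(sentence_a$samples, sentence_b$samples)
  }
  if (same) stop_domain(
    "sentence_a and sentence_b must be distinct sentences")
  cfg_plain <- cfg; cfg_plain$flip <- FALSE
  cfg_flip <- cfg; cfg_flip$flip <- TRUE
  a_cfg <- if (kind == "intelligible") cfg_plain else cfg_flip
  sv_a <- vocode(sentence_a, a_cfg)
  sv_b <- vocode(sentence_b, cfg_flip)
  mix_at_snr(sv_a, sv_b, cond$snr_db, rms_ref = rms_ref)
}

#' Build a "scratchy" target sound
#'
#' The attention-check target of the naive-listening paradigm: two
#' sentences are frequency-flipped sine-vocoded, mixed at 0 dB, and the
#' result is *noise*-vocoded on the same filterbank (band envelopes
#' multiplied by band-limited noise carriers instead of tone carriers),
#' which gives it a denser spectrum and a different timbre than the
#' sine-vocoded stimuli.
#'
#' @param sentence_a,sentence_b distinct [audio_signal()] sentences.
#' @param cfg a [vocoder_config()].
#' @param seed integer seed for the noise carriers.
#' @param rms_ref reference RMS of the finished sound.
#' @return an [audio_signal()].
#' @export
make_target_sound <- function(sentence_a, sentence_b, cfg, seed = 1,
                              rms_ref = 0.05) {
  same <- if (!is.null(sentence_a$id) && !is.null(sentence_b$id)) {
    identical(sentence_a$id, sentence_b$id)
  } else {
    identical(sentence_a$samples, sentence_b$samples)
  }
  if (same) stop_domain(
    "sentence_a and sentence_b must be distinct sentences")
  cfg_flip <- cfg; cfg_flip$flip <- TRUE
  sv_a <- vocode(sentence_a, cfg_flip)
  sv_b <- vocode(sentence_b, cfg_flip)
  base <- mix_at_snr(sv_a, sv_b, 0, rms_ref = rms_ref)
  fb <- cfg$filterbank
  n <- length(base$samples)
  out <- numeric(n)
  noise <- with_seed(derive_seed(seed, "target-noise"), rnorm(n))
  for (b in seq_len(fb$n_bands)) {
    analysis <- sos_filter(fb$filters[[b]], base$samples)
    rms_a <- rms(analysis)
    if (rms_a == 0) next
    env <- sos_filter(cfg$env_filter, pmax(analysis, 0))
    carrier <- sos_filter(fb$filters[[b]], noise)
    synth <- sos_filter(fb$filters[[b]], env * carrier)
    rms_s <- rms(synth)
    if (rms_s > 0) synth <- synth * (rms_a / rms_s)
    out <- out + synth
  }
  normalize_rms(audio_signal(out, fb$sample_rate), rms_ref)
}

#' Stimulus condition
#'
#' One cell of the stimulus grid: band count, SNR and trial kind.
#'
#' @param n_bands 8 or 16.
#' @param snr_db one of -6, -3, 0, 3, 6 dB.
#' @param kind `"intelligible"` or `"unintelligible"`.
#' @return an object of class `stimulus_condition`.
#' @export
stimulus_condition <- function(n_bands, snr_db,
                               kind = c("intelligible", "unintelligible")) {
  kind <- match.arg(kind)
  if (!n_bands %in% c(8, 16)) stop_domain("n_bands must be 8 or 16")
  if (!snr_db %in% c(-6, -3, 0, 3, 6)) stop_domain(
    "snr_db must be on the grid {-6, -3, 0, 3, 6}")
  structure(list(n_bands = n_bands, snr_db = snr_db, kind = kind),
            class = "stimulus_condition")
}

#' The full stimulus-condition grid
#'
#' All combinations of band count (8, 16), SNR (+6 to -6 dB in 3 dB
#' steps) and trial kind: 10 acoustic conditions per kind.
#'
#' @return a data.frame with columns `n_bands`, `snr_db`, `kind`.
#' @export
stimulus_grid <- function() {
  g <- expand.grid(n_bands = c(8, 16), snr_db = c(-6, -3, 0, 3, 6),
                   kind = c("intelligible", "unintelligible"),
                   stringsAsFactors = FALSE)
  g[order(g$kind, g$n_bands, g$snr_db), , drop = FALSE]
}

#' Spectral flatness of a signal
#'
#' Geometric mean over arithmetic mean of the power spectrum (Wiener
#' entropy); 1 for white noise, near 0 for sparse line spectra.
#'
#' @param x an [audio_signal()] or numeric vector.
#' @param eps floor added to the power spectrum for numerical safety.
#' @return scalar in (0, 1\].
#' @export
spectral_flatness <- function(x, eps = 1e-12) {
  if (inherits(x, "audio_signal")) x <- x$samples
  p <- Mod(stats::fft(x))^2
  p <- p[seq_len(floor(length(p) / 2))] + eps
  exp(mean(log(p))) / mean(p)
}
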