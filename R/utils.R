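#' Derive a reproducible sub-stream seed
#'
#' All randomness in the package flows from one root seed. Sub-streams
#' (per observer, per trial block, per replicate) use seeds derived from
#' the root seed and a string key with a small multiplicative hash, so
#' that adding one simulated component never perturbs the draws of
#' another. All arithmetic stays below 2^53 so the result is exact.
#'
#' @param seed integer root seed.
#' @param ... components (coerced to character) identifying the stream.
#' @return an integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(...), collapse = "/")
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer((abs(as.numeric(seed)) %% 2147483647 * 48271 + h) %% 2147483647)
}

# Run code with a local RNG state: seed is set inside, the caller's
# .Random.seed is restored on exit.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Root-mean-square level of a waveform
#'
#' @param x numeric vector (or [audio_signal()]).
#' @return scalar RMS.
#' @export
rms <- function(x) {
  if (inherits(x, "audio_signal")) x <- x$samples
  sqrt(mean(x^2))
}

stop_domain <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
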