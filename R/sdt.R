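#' Extreme-rate correction for hit / false-alarm proportions
#'
#' The standard correction for rates of exactly 0 or 1 before the
#' z-transform: 0 successes becomes `0.5/n` and `n` successes becomes
#' `(n - 0.5)/n`; anything in between is the plain proportion. Applied
#' per rate, using that rate's own trial count.
#'
#' @param successes integer count(s) of "yes" responses, `0 <= successes
#'   <= n`.
#' @param n trial count(s), >= 1.
#' @return corrected proportion(s) strictly inside (0, 1).
#' @examples
#' correct_rate(45, 45) # (45 - 0.5)/45
#' correct_rate(0, 45)  # 0.5/45
#' @export
correct_rate <- function(successes, n) {
  if (any(n < 1)) stop_domain("n must be >= 1")
  if (any(successes < 0 | successes > n)) stop_domain(
    "successes must lie in [0, n]")
  n <- rep_len(n, length(successes))
  p <- successes / n
  zero <- successes == 0
  full <- successes == n
  p[zero] <- 0.5 / n[zero]
  p[full] <- (n[full] - 0.5) / n[full]
  p
}

#' Signal-detection outcome from yes/no counts
#'
#' Equal-variance Gaussian SDT on corrected rates H and F:
#' \deqn{d' = z(H) - z(F), \quad C = -(z(H) + z(F))/2, \quad
#'   \beta = e^{d' C},}
#' where z is the standard-normal quantile. \eqn{\beta} is the
#' likelihood ratio of the signal and noise densities at the decision
#' criterion, algebraically equal to \eqn{\phi(z(H))/\phi(z(F))}.
#' All inputs may be vectors (one outcome per element).
#'
#' @param hits,n_signal hit count and number of signal trials.
#' @param false_alarms,n_noise false-alarm count and number of noise
#'   trials.
#' @return a data.frame with columns `hit_rate`, `fa_rate`, `d_prime`,
#'   `criterion_c`, `beta`.
#' @examples
#' sdt_outcome(38, 45, 9, 45)
#' @export
sdt_outcome <- function(hits, n_signal, false_alarms, n_noise) {
  if (any(n_signal < 1) || any(n_noise < 1)) stop_domain(
    "n_signal and n_noise must be >= 1")
  H <- correct_rate(hits, n_signal)
  F_ <- correct_rate(false_alarms, n_noise)
  zH <- stats::qnorm(H)
  zF <- stats::qnorm(F_)
  d <- zH - zF
  C <- -(zH + zF) / 2
  data.frame(hit_rate = H, fa_rate = F_, d_prime = d, criterion_c = C,
             beta = exp(d * C))
}

#' Pre-to-post change in signal-detection measures
#'
#' @param pre,post single-row outcome data.frames from [sdt_outcome()]
#'   (or equal-length multi-row frames, matched row-wise), belonging to
#'   the same observer and condition. If both carry a `participant`
#'   column it must match.
#' @return a data.frame with columns `delta_d_prime`,
#'   `delta_criterion_c`, `delta_beta` (plus `participant` when
#'   present).
#' @export
change_scores <- function(pre, post) {
  if (nrow(pre) != nrow(post)) stop_domain(
    "pre and post must have the same number of rows")
  out <- data.frame(delta_d_prime = post$d_prime - pre$d_prime,
                    delta_criterion_c = post$criterion_c - pre$criterion_c,
                    delta_beta = post$beta - pre$beta)
  if (!is.null(pre$participant) || !is.null(post$participant)) {
    if (!identical(as.character(pre$participant),
                   as.character(post$participant))) stop_domain(
      "pre and post belong to different participants")
    out <- cbind(participant = pre$participant, out)
  }
  out
}

#' Signal-detection outcomes from a long response table
#'
#' Aggregates per-trial yes/no responses into per
#' participant x phase (x condition) counts and computes
#' [sdt_outcome()] for each cell. Intelligible trials marked as
#' containing speech are hits; unintelligible trials so marked are
#' false alarms.
#'
#' @param responses data.frame with columns `participant`, `phase`,
#'   `kind` (`intelligible`/`unintelligible`), `said_speech` (logical
#'   or 0/1), and optionally `condition`.
#' @return a data.frame with one row per cell: `participant`, `phase`,
#'   (`condition`,) counts and the SDT measures.
#' @export
sdt_from_responses <- function(responses) {
  need <- c("participant", "phase", "kind", "said_speech")
  if (!all(need %in% names(responses))) stop_domain(
    "responses must have columns %s", paste(need, collapse = ", "))
  keys <- c("participant", "phase",
            intersect("condition", names(responses)))
  responses$said_speech <- as.integer(responses$said_speech)
  sig <- responses[responses$kind == "intelligible", ]
  noi <- responses[responses$kind == "unintelligible", ]
  agg <- function(d) stats::aggregate(
    d["said_speech"], d[keys],
    FUN = function(v) c(sum(v), length(v)))
  s <- agg(sig); n <- agg(noi)
  s$hits <- s$said_speech[, 1]; s$n_signal <- s$said_speech[, 2]
  n$false_alarms <- n$said_speech[, 1]; n$n_noise <- n$said_speech[, 2]
  m <- merge(s[c(keys, "hits", "n_signal")],
             n[c(keys, "false_alarms", "n_noise")], by = keys)
  cbind(m, sdt_outcome(m$hits, m$n_signal, m$false_alarms, m$n_noise))
}
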