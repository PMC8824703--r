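#' Greenwood cochlear frequency-position map
#'
#' The Greenwood function relates a normalized place on the basilar
#' membrane \eqn{x \in [0, 1]} (0 = apex, 1 = base) to its characteristic
#' frequency \eqn{F(x) = A (10^{a x} - k)}. Filterbanks spaced at "equal
#' basilar membrane distance" place their band edges uniformly in
#' \eqn{x}. Defaults are the standard human constants with position
#' normalized to the full cochlear length.
#'
#' @param A scale constant in Hz (> 0).
#' @param a exponent constant per unit normalized position (> 0).
#' @param k integration constant, `0 <= k < 1`.
#' @return an object of class `greenwood_map`.
#' @examples
#' m <- greenwood_map()
#' greenwood_frequency(0.5, m)
#' greenwood_position(1000, m)
#' @export
greenwood_map <- function(A = 165.4, a = 2.1, k = 0.88) {
  if (!(A > 0)) stop_domain("A must be > 0 (got %g)", A)
  if (!(a > 0)) stop_domain("a must be > 0 (got %g)", a)
  if (!(k >= 0 && k < 1)) stop_domain("k must lie in [0, 1) (got %g)", k)
  structure(list(A = A, a = a, k = k), class = "greenwood_map")
}

#' @export
print.greenwood_map <- function(x, ...) {
  cat(sprintf(
    "Greenwood map: F(x) = %g * (10^(%g x) - %g), F(0) = %.3f Hz, F(1) = %.1f Hz\n",
    x$A, x$a, x$k, greenwood_frequency(0, x), greenwood_frequency(1, x)))
  invisible(x)
}

#' Characteristic frequency at a basilar-membrane position
#'
#' @param x normalized position(s) in `[0, 1]`.
#' @param map a [greenwood_map()].
#' @return frequency in Hz.
#' @export
greenwood_frequency <- function(x, map = greenwood_map()) {
  if (any(x < 0 | x > 1)) stop_domain(
    "position must lie in [0, 1]; got values outside (min %g, max %g)",
    min(x), max(x))
  map$A * (10^(map$a * x) - map$k)
}

#' Basilar-membrane position of a frequency
#'
#' Inverse of [greenwood_frequency()]:
#' \eqn{x = \log_{10}(f/A + k) / a}.
#'
#' @param f frequency(ies) in Hz; must lie within the map's range
#'   `[F(0), F(1)]`.
#' @param map a [greenwood_map()].
#' @return normalized position(s) in `[0, 1]`.
#' @export
greenwood_position <- function(f, map = greenwood_map()) {
  lo <- greenwood_frequency(0, map)
  hi <- greenwood_frequency(1, map)
  if (any(f < lo | f > hi)) stop_domain(
    "frequency outside the map's range [%.3f, %.1f] Hz", lo, hi)
  log10(f / map$A + map$k) / map$a
}
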