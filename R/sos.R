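# Butterworth IIR design in zero-pole-gain form, realized as a cascade
# of second-order sections (biquads). The direct polynomial (b, a) form
# that signal::butter() returns is numerically unstable for high-order
# bandpass filters at low normalized frequencies (the lowest Greenwood
# band is 100-200 Hz at fs = 22050), so the package designs filters
# itself: analog Butterworth prototype -> lowpass/bandpass transform ->
# bilinear transform -> conjugate-paired biquads. Each biquad is run
# with signal::filter(); stability (all poles strictly inside the unit
# circle) is asserted at design time.

# Analog lowpass prototype poles for order n (unit cutoff).
butter_prototype <- function(n) {
  k <- seq_len(n)
  theta <- pi * (2 * k - 1) / (2 * n)
  complex(real = -sin(theta), imaginary = cos(theta))
}

bilinear_zpk <- function(z, p, k, fs) {
  fs2 <- 2 * fs
  degree <- length(p) - length(z)
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  kd <- k * Re(prod(fs2 - z) / prod(fs2 - p))
  list(z = c(zd, rep(-1 + 0i, degree)), p = pd, k = kd)
}

# Pair conjugate roots into quadratic factors; returns a matrix with one
# row per section, columns c0 c1 c2 of c0 + c1 z^-1 + c2 z^-2.
roots_to_biquads <- function(r) {
  pos <- r[Im(r) > 1e-12]
  real <- sort(Re(r[abs(Im(r)) <= 1e-12]))
  sec <- list()
  for (q in pos) sec[[length(sec) + 1]] <- c(1, -2 * Re(q), Mod(q)^2)
  while (length(real) >= 2) {
    sec[[length(sec) + 1]] <- c(1, -(real[1] + real[2]), real[1] * real[2])
    real <- real[-(1:2)]
  }
  if (length(real) == 1) sec[[length(sec) + 1]] <- c(1, -real[1], 0)
  do.call(rbind, sec)
}

# Build the cascade from numerator sections and pole sections, with the
# overall gain set so that |H(f_ref)| = 1. Pole sections are ordered by
# increasing radius, the conventional ordering that keeps intermediate
# section outputs tame.
new_sos_filter <- function(b, a, fs, f_ref) {
  while (nrow(b) < nrow(a)) b <- rbind(b, c(1, 0, 0))
  a <- a[order(vapply(seq_len(nrow(a)), function(i)
    max(Mod(polyroot(rev(a[i, ])))), 0)), , drop = FALSE]
  flt <- structure(list(b = b, a = a, gain = 1, fs = fs), class = "sos_filter")
  g <- abs(sos_response(flt, f_ref))
  flt$gain <- 1 / g
  poles <- unlist(lapply(seq_len(nrow(a)), function(i) Mod(polyroot(rev(a[i, ])))))
  if (any(poles >= 1)) stop_domain(
    "designed filter is unstable (max pole radius %g)", max(poles))
  flt
}

#' Butterworth bandpass as a biquad cascade
#'
#' Designs a digital Butterworth bandpass of the given prototype order
#' (final order `2 * order`) with the two -3 dB edges placed exactly at
#' `f_lo` and `f_hi` via pre-warped bilinear transform. Gain is
#' normalized to 1 at the band's geometric-mean frequency.
#'
#' @param order lowpass prototype order (6 gives the usual "sixth-order
#'   Butterworth" band definition).
#' @param f_lo,f_hi band edges in Hz.
#' @param fs sample rate in Hz.
#' @return an object of class `sos_filter`.
#' @export
butter_bandpass <- function(order, f_lo, f_hi, fs) {
  if (!(f_lo > 0 && f_lo < f_hi && f_hi < fs / 2)) stop_domain(
    "need 0 < f_lo < f_hi < fs/2 (got %g, %g at fs = %g)", f_lo, f_hi, fs)
  w1 <- 2 * fs * tan(pi * f_lo / fs)
  w2 <- 2 * fs * tan(pi * f_hi / fs)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1
  p_lp <- butter_prototype(order)
  s <- p_lp * bw / 2
  p_bp <- c(s + sqrt(s^2 - w0^2), s - sqrt(s^2 - w0^2))
  d <- bilinear_zpk(rep(0 + 0i, order), p_bp, 1, fs)
  # digital zeros: `order` at z = +1 and `order` at z = -1; give every
  # section one of each, i.e. the bandpass numerator 1 - z^-2
  b <- matrix(rep(c(1, 0, -1), order), ncol = 3, byrow = TRUE)
  f_ref <- fs / pi * atan(w0 / (2 * fs)) # image of analog centre freq
  new_sos_filter(b, roots_to_biquads(d$p), fs, f_ref)
}

#' Butterworth lowpass as a biquad cascade
#'
#' Digital Butterworth lowpass with its -3 dB point exactly at `f_c`
#' (pre-warped bilinear design); unity DC gain.
#'
#' @param order filter order.
#' @param f_c cutoff (-3 dB) frequency in Hz.
#' @param fs sample rate in Hz.
#' @return an object of class `sos_filter`.
#' @export
butter_lowpass <- function(order, f_c, fs) {
  if (!(f_c > 0 && f_c < fs / 2)) stop_domain(
    "need 0 < f_c < fs/2 (got %g at fs = %g)", f_c, fs)
  wc <- 2 * fs * tan(pi * f_c / fs)
  p <- butter_prototype(order) * wc
  d <- bilinear_zpk(complex(0), p, 1, fs)
  new_sos_filter(roots_to_biquads(d$z), roots_to_biquads(d$p), fs, f_ref = 0)
}

#' Complex frequency response of a biquad cascade
#'
#' @param flt an `sos_filter`.
#' @param f frequencies in Hz.
#' @return complex response H(f).
#' @export
sos_response <- function(flt, f) {
  w <- 2 * pi * f / flt$fs
  e1 <- exp(-1i * w)
  e2 <- exp(-2i * w)
  H <- rep(flt$gain + 0i, length(f))
  for (i in seq_len(nrow(flt$a))) {
    H <- H * (flt$b[i, 1] + flt$b[i, 2] * e1 + flt$b[i, 3] * e2) /
      (flt$a[i, 1] + flt$a[i, 2] * e1 + flt$a[i, 3] * e2)
  }
  H
}

#' Apply a biquad-cascade filter to a signal
#'
#' Forward-only (causal) filtering, section by section.
#'
#' @param flt an `sos_filter`.
#' @param x numeric vector.
#' @return filtered vector, same length as `x`.
#' @export
sos_filter <- function(flt, x) {
  for (i in seq_len(nrow(flt$a))) {
    x <- as.numeric(signal::filter(flt$b[i, ], flt$a[i, ], x))
  }
  x * flt$gain
}

#' @export
print.sos_filter <- function(x, ...) {
  cat(sprintf("Biquad cascade: %d sections, fs = %g Hz, gain = %.6g\n",
              nrow(x$a), x$fs, x$gain))
  invisible(x)
}

#' Locate the -3 dB point of a lowpass filter response
#'
#' Evaluates the magnitude response on a fine grid and refines the
#' -3 dB crossing by bisection.
#'
#' @param flt an `sos_filter` with lowpass character (unity DC gain).
#' @param f_max upper edge of the search interval in Hz.
#' @param n grid resolution.
#' @return frequency in Hz where |H| crosses 1/sqrt(2).
#' @export
measure_cutoff <- function(flt, f_max = flt$fs / 2, n = 20000) {
  target <- 1 / sqrt(2)
  f <- seq(0, f_max, length.out = n)
  mag <- abs(sos_response(flt, f))
  i <- which(mag < target)[1]
  if (is.na(i) || i == 1) stop_domain("no -3 dB crossing below %g Hz", f_max)
  uniroot(function(fr) abs(sos_response(flt, fr)) - target,
          lower = f[i - 1], upper = f[i], tol = 1e-9)$root
}
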