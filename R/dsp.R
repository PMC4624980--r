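# IIR filter design and zero-phase filtering in second-order sections.
# Base-R implementations (bilinear transform of analytic analog prototypes);
# the design path mirrors the classical textbook recipes.

#' Chebyshev type-I lowpass design in second-order sections
#'
#' Designs a digital Chebyshev type-I lowpass filter by bilinear transform of
#' the analog all-pole prototype.
#'
#' @param n filter order.
#' @param rp passband ripple in dB.
#' @param wc cutoff (passband edge) as a fraction of the Nyquist frequency,
#'   in (0, 1).
#' @return A second-order-section filter: list with matrices `b` and `a`
#'   (one row per section, columns are the 3 coefficients; `a[,1] == 1`).
#' @keywords internal
cheby1_sos <- function(n, rp, wc) {
  stopifnot(n >= 1, rp > 0, wc > 0, wc < 1)
  eps <- sqrt(10^(rp / 10) - 1)
  mu <- asinh(1 / eps) / n
  k <- seq_len(n)
  theta <- pi * (2 * k - 1) / (2 * n)
  p <- complex(real = -sinh(mu) * sin(theta), imaginary = cosh(mu) * cos(theta))
  gain <- Re(prod(-p))
  if (n %% 2 == 0) gain <- gain / sqrt(1 + eps^2)
  # lowpass-to-lowpass frequency scaling with bilinear prewarping (fs = 2)
  warped <- 4 * tan(pi * wc / 2)
  p <- p * warped
  gain <- gain * warped^n
  zpk_bilinear_sos(p, z0 = -1, gain = gain)
}

#' Butterworth design in second-order sections
#'
#' @param n filter order.
#' @param wc cutoff as a fraction of Nyquist.
#' @param type `"low"` or `"high"`.
#' @return Second-order-section filter (see [cheby1_sos()]).
#' @keywords internal
butter_sos <- function(n, wc, type = c("low", "high")) {
  type <- match.arg(type)
  stopifnot(n >= 1, wc > 0, wc < 1)
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  gain <- 1
  warped <- 4 * tan(pi * wc / 2)
  if (type == "low") {
    p <- p * warped
    gain <- warped^n
    z0 <- -1
  } else {
    gain <- Re(prod(-p))   # lp2hp gain: prod(-p)/prod(-z), no zeros
    p <- warped / p
    z0 <- 1                # analog zeros at 0 map to z = +1
    nz0 <- n
  }
  zpk_bilinear_sos(p, z0 = z0, gain = gain, nz0 = if (type == "high") n else 0)
}

# Bilinear transform (fs = 2) of an analog filter with `nz0` zeros at s = 0
# (the rest at infinity) whose digital zeros all land on a single real point
# z0, then pairing into biquads.
zpk_bilinear_sos <- function(p, z0, gain, nz0 = 0) {
  n <- length(p)
  fs2 <- 4
  zp <- (fs2 + p) / (fs2 - p)
  gz <- gain * Re(fs2^nz0 / prod(fs2 - p))
  # pair conjugate poles; at most one real pole (odd order)
  cplx <- zp[Im(zp) > 1e-12]
  realp <- Re(zp[abs(Im(zp)) <= 1e-12])
  nsec <- length(cplx) + length(realp)
  b <- matrix(0, nsec, 3)
  a <- matrix(0, nsec, 3)
  i <- 0
  for (pp in cplx) {
    i <- i + 1
    a[i, ] <- c(1, -2 * Re(pp), Mod(pp)^2)
    b[i, ] <- c(1, -2 * z0, z0^2)
  }
  for (pr in realp) {
    i <- i + 1
    a[i, ] <- c(1, -pr, 0)
    b[i, ] <- c(1, -z0, 0)
  }
  b[1, ] <- b[1, ] * gz
  list(b = b, a = a)
}

# Single-pass SOS filtering with zero initial conditions, vectorised through
# stats::filter (C implementations of the MA and AR recursions).
sosfilt <- function(sos, x) {
  y <- as.numeric(x)
  for (s in seq_len(nrow(sos$b))) {
    bb <- sos$b[s, ]
    aa <- sos$a[s, ]
    v <- stats::filter(y, bb, method = "convolution", sides = 1)
    v <- as.numeric(v)
    v[1] <- bb[1] * y[1]
    if (length(y) >= 2) v[2] <- bb[1] * y[2] + bb[2] * y[1]
    y <- as.numeric(stats::filter(v, -aa[2:3], method = "recursive"))
  }
  y
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies a second-order-section filter forward and backward with odd
#' reflection padding at both ends, giving zero phase distortion and the
#' squared magnitude response.
#'
#' @param sos filter from [cheby1_sos()] or [butter_sos()].
#' @param x numeric vector.
#' @return Filtered vector, same length as `x`.
#' @keywords internal
filtfilt_sos <- function(sos, x) {
  n <- length(x)
  pad <- min(3 * (2 * nrow(sos$b) + 1), n - 1)
  if (pad < 1) stop("input too short to filter")
  head_ext <- 2 * x[1] - x[(pad + 1):2]
  tail_ext <- 2 * x[n] - x[(n - 1):(n - pad)]
  xe <- c(head_ext, x, tail_ext)
  y <- sosfilt(sos, xe)
  y <- rev(sosfilt(sos, rev(y)))
  y[(pad + 1):(pad + n)]
}

# Chebyshev-I order to meet a passband edge wp (ripple rp dB) and stopband
# edge ws (attenuation as dB), both as fractions of Nyquist.
cheb1_order <- function(wp, ws, rp = 1, as = 40) {
  sel <- tan(pi * ws / 2) / tan(pi * wp / 2)
  num <- acosh(sqrt((10^(as / 10) - 1) / (10^(rp / 10) - 1)))
  max(1L, as.integer(ceiling(num / acosh(sel))))
}

# Frequency response magnitude of an SOS filter at frequencies f (Hz) for
# sampling rate `rate`.
sos_gain <- function(sos, f, rate) {
  w <- 2 * pi * f / rate
  z <- exp(-1i * w)
  h <- rep(1 + 0i, length(w))
  for (s in seq_len(nrow(sos$b))) {
    num <- sos$b[s, 1] + sos$b[s, 2] * z + sos$b[s, 3] * z^2
    den <- sos$a[s, 1] + sos$a[s, 2] * z + sos$a[s, 3] * z^2
    h <- h * num / den
  }
  Mod(h)
}

# Linear-interpolation resampling of a uniformly sampled vector from rate
# `from` to rate `to`; sample k (1-based) sits at time (k-1)/rate.
resample_linear <- function(x, from, to) {
  n <- length(x)
  dur <- (n - 1) / from
  t_new <- seq(0, dur, by = 1 / to)
  stats::approx(x = seq(0, dur, length.out = n), y = x, xout = t_new,
                rule = 2)$y
}
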