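# DSP primitives: analytic Butterworth magnitude responses applied zero-phase
# in the frequency domain, and the FFT Hilbert transform.
#
# Filtering strategy: rather than discretising the Butterworth prototype with
# a bilinear transform and running it forward-backward, we apply the
# *analytic* magnitude response squared (the forward-backward gain of the
# stated filter) directly in the frequency domain after reflection padding.
# This is exactly zero-phase, matches the closed-form response oracle by
# construction, and avoids IIR transient handling. The effective roll-off is
# twice the nominal order, as with any forward-backward scheme.

#' Analytic Butterworth band-pass magnitude response
#'
#' \eqn{|H(f)|^2 = 1 / (1 + (Q (f/f_0 - f_0/f))^{2n})} with centre
#' \eqn{f_0 = \sqrt{f_l f_h}} and \eqn{Q = f_0/(f_h - f_l)}; -3 dB points at
#' the band edges.
#'
#' @param f frequencies (Hz), vectorised; `f = 0` maps to gain 0.
#' @param low,high band edges (Hz).
#' @param order filter order `n`.
#' @return magnitude gain `|H(f)|` in `[0, 1]`.
#' @export
butter_bandpass_gain <- function(f, low, high, order = 1L) {
  stopifnot(low > 0, high > low)
  f0 <- sqrt(low * high)
  q <- f0 / (high - low)
  x <- ifelse(f <= 0, Inf, q * abs(f / f0 - f0 / f))
  sqrt(1 / (1 + x^(2 * order)))
}

#' Analytic Butterworth band-stop magnitude response
#'
#' Complement of the band-pass prototype: gain 1 far from the band, exact
#' null at the centre frequency \eqn{f_0 = \sqrt{f_l f_h}}.
#'
#' @inheritParams butter_bandpass_gain
#' @return magnitude gain in `[0, 1]`.
#' @export
butter_bandstop_gain <- function(f, low, high, order = 1L) {
  stopifnot(low > 0, high > low)
  f0 <- sqrt(low * high)
  q <- f0 / (high - low)
  x <- ifelse(f <= 0, Inf, q * abs(f / f0 - f0 / f))
  x2n <- x^(2 * order)
  sqrt(ifelse(is.infinite(x2n), 1, x2n / (1 + x2n)))
}

# Apply a real, even frequency-domain gain to each row of a channels x samples
# matrix (or to a vector). Reflection padding suppresses wrap-around; the
# applied gain is gain_fun(f)^2, i.e. the forward-backward response.
.fft_filter <- function(x, rate, gain_fun, pad_s = 2) {
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, nrow = 1L) else x
  n <- ncol(m)
  npad <- min(n - 1L, as.integer(round(pad_s * rate)))
  ntot <- stats::nextn(n + 2L * npad, c(2L, 3L, 5L))
  extra <- ntot - (n + 2L * npad)
  # frequency axis of the padded length
  f <- seq_len(ntot) - 1L
  f <- f * rate / ntot
  f <- pmin(f, rate - f)
  g <- gain_fun(f)^2
  out <- matrix(0, nrow(m), n)
  for (i in seq_len(nrow(m))) {
    xi <- m[i, ]
    left <- if (npad > 0L) xi[npad:1L + 1L] else numeric() # reflect, drop end
    right <- if (npad > 0L) xi[n - 1L - (seq_len(npad) - 1L)] else numeric()
    xp <- c(left, xi, right, numeric(extra))
    yp <- Re(stats::fft(stats::fft(xp) * g, inverse = TRUE)) / ntot
    out[i, ] <- yp[npad + seq_len(n)]
  }
  if (vec) out[1L, ] else out
}

#' Hilbert envelope of a real signal
#'
#' Modulus of the analytic signal computed with the FFT method: the negative
#' frequencies of the spectrum are zeroed (positive doubled) and the inverse
#' transform's modulus is returned. For a band-limited oscillation
#' `A(t) sin(2 pi f t)` with slowly varying `A`, the envelope tracks `A(t)`
#' away from the series edges; callers are expected to trim edge samples
#' (see [extract_window()]).
#'
#' @param x numeric vector, no NA in the unmasked region.
#' @return non-negative numeric vector, same length.
#' @export
hilbert_envelope <- function(x) {
  if (all(!is.finite(x))) stop("hilbert_envelope: all-masked input")
  if (anyNA(x)) stop("hilbert_envelope: NA in input")
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE)) / n
}

# Hann window (periodic=FALSE, symmetric), used by the burst generator
.hanning <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
}
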