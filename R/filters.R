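# Powerline notch filtering.
#
# Second-order IIR notch (RBJ biquad, quality factor 30) per frequency,
# applied forward-backward (zero phase) so window timestamps are unaffected.

biquad_notch_coefs <- function(freq, fs, Q = 30) {
  w0 <- 2 * pi * freq / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# Single-pass IIR filtering built on stats::filter (C speed): the
# moving-average part then the recursive part. Initial conditions are the
# steady state for a constant input equal to the first sample, so a constant
# signal passes without a start-up transient (the same convention zero-phase
# filtering routines use).
iir_filter <- function(x, b, a) {
  nb <- length(b)
  v <- stats::filter(c(rep(x[1], nb - 1), x), b, method = "convolution",
                     sides = 1)
  v <- as.numeric(v)[nb:(nb + length(x) - 1)]
  y_ss <- x[1] * sum(b) / sum(a)
  as.numeric(stats::filter(v, -a[-1], method = "recursive",
                           init = rep(y_ss, length(a) - 1)))
}

# Zero-phase application: odd-reflection padding, forward pass, reversed
# backward pass, crop.
filtfilt_biquad <- function(x, b, a) {
  n <- length(x)
  pad <- min(n - 1, 9L)
  if (pad > 0) {
    head_pad <- 2 * x[1] - x[(pad + 1):2]
    tail_pad <- 2 * x[n] - x[(n - 1):(n - pad)]
    xe <- c(head_pad, x, tail_pad)
  } else xe <- x
  y <- iir_filter(xe, b, a)
  y <- rev(iir_filter(rev(y), b, a))
  y[(pad + 1):(pad + n)]
}

#' Notch-filter powerline contamination out of a signal
#'
#' Applies one zero-phase second-order IIR notch per frequency (quality
#' factor `Q`), preserving signal length and timing.
#'
#' @param samples numeric vector.
#' @param fs sampling rate, Hz; must exceed twice the largest notch frequency.
#' @param freqs frequencies to remove, Hz (default 50 and 100 Hz, mains
#'   fundamental and first harmonic).
#' @param Q quality factor of each notch.
#' @return Filtered numeric vector, same length as the input.
#' @export
notch_filter <- function(samples, fs, freqs = c(50, 100), Q = 30) {
  stopifnot_scalar_num(fs, "fs", positive = TRUE)
  if (!length(freqs)) return(samples)
  if (any(freqs <= 0) || any(freqs >= fs / 2))
    config_error("notch frequencies must lie strictly below the Nyquist rate")
  y <- as.numeric(samples)
  for (f in freqs) {
    co <- biquad_notch_coefs(f, fs, Q)
    y <- filtfilt_biquad(y, co$b, co$a)
  }
  y
}
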