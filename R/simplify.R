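# Signal simplification: S-second windows -> N-sample rolling median ->
# decimation by F. The rolling median removes the high-frequency content
# (noise or non-discriminative variation) while preserving the envelope, so
# no extra anti-alias filter is applied before decimation.

#' Rolling median of a signal
#'
#' Centered window of `N` samples, truncated (shrinking) at both edges so the
#' output has the input's length. The median is exact: even-sized windows
#' return the arithmetic mean of the two middle order statistics.
#'
#' @param samples numeric vector.
#' @param N window size in samples (>= 1).
#' @return Numeric vector of the same length.
#' @export
rolling_median <- function(samples, N) {
  if (!is.numeric(N) || length(N) != 1 || N < 1 || N != round(N))
    config_error("`N` must be a positive integer")
  rolling_median_cpp(as.numeric(samples), as.integer(N))
}

#' Decimate a signal by an integer factor
#'
#' Keeps every `F`-th sample starting at the first; output length is
#' `ceiling(length(samples) / F)`. No anti-alias filter is applied — the
#' rolling median preceding it in the simplification chain is the smoother.
#'
#' @param samples numeric vector.
#' @param F decimation factor (>= 1).
#' @return Numeric vector.
#' @export
downsample <- function(samples, F) {
  if (!is.numeric(F) || length(F) != 1 || F < 1 || F != round(F))
    config_error("`F` must be a positive integer")
  samples[seq(1, length(samples), by = F)]
}

#' Simplify a recording into smoothed, decimated windows
#'
#' The full simplification transform: cut the signal into non-overlapping
#' windows of `S` seconds, apply an `N`-sample rolling median within each
#' window, then decimate by `F`. Defaults are the values found to preserve
#' the signal envelope at one tenth of the original granularity
#' (S = 16 s, N = 50, F = 10). The trailing partial window is discarded.
#'
#' @param rec a [recording()].
#' @param S window length, seconds.
#' @param N rolling-median window, samples.
#' @param F decimation factor.
#' @return A [window_set()] with `fs_effective = fs / F` and labels `-1`.
#' @export
simplify <- function(rec, S = 16, N = 50, F = 10) {
  stopifnot_scalar_num(S, "S", positive = TRUE)
  if (N < 1 || N != round(N)) config_error("`N` must be a positive integer")
  if (F < 1 || F != round(F)) config_error("`F` must be a positive integer")
  win_len <- round(S * rec$fs)
  n_win <- floor(length(rec$samples) / win_len)
  keep <- seq(1, win_len, by = F)
  if (n_win == 0) {
    warning("recording shorter than one window; empty window set")
    return(window_set(matrix(numeric(0), 0, length(keep)), character(0),
                      numeric(0), integer(0), rec$fs / F, S))
  }
  m <- matrix(rec$samples[seq_len(n_win * win_len)], nrow = n_win,
              byrow = TRUE)
  m <- rolling_median_rows_cpp(m, as.integer(N))[, keep, drop = FALSE]
  window_set(m, rep(rec$plant_id, n_win),
             rec$t0 + (seq_len(n_win) - 1) * S,
             rep(-1L, n_win), rec$fs / F, S)
}
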