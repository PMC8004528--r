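# Band-pass filtering conventions. Reference estimators use linear-phase FIR
# filters applied zero-phase (forward-backward); the eMI low-frequency
# extraction uses a 4th-order Butterworth, also zero-phase.

# Zero-phase application of a symmetric FIR filter b to the columns of x
# (vector or matrix), implemented in the frequency domain as |B(f)|^2 with
# zero padding. For a linear-phase FIR this equals forward-backward
# filtering with zero-padded edges.
fir_zerophase <- function(x, b) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  n <- nrow(x)
  ord <- length(b) - 1L
  nfft <- next_fast_n(n + 2L * ord)
  H <- Mod(stats::fft(c(b, numeric(nfft - length(b)))))^2
  xp <- rbind(x, matrix(0, nfft - n, ncol(x)))
  y <- Re(stats::mvfft(stats::mvfft(xp) * H, inverse = TRUE)) / nfft
  y <- y[1:n, , drop = FALSE]
  if (vec) drop(y) else y
}

# FIR order used by the reference methods: samples in three cycles of the
# band's low edge
fir_order_3cyc <- function(fs, lo) max(8L, round(3 * fs / lo))

#' Zero-phase FIR band-pass filter
#'
#' Windowed-sinc band-pass filter of order equal to the number of samples in
#' three cycles of the band's low edge, applied forward-backward so the net
#' phase response is zero. This is the filtering convention of the reference
#' PAC estimators.
#'
#' @param x a [pac_ts()].
#' @param band numeric `c(lo, hi)` in Hz, inside `(0, fs/2)`.
#' @return a filtered [pac_ts()].
#' @export
fir_bandpass_two_way <- function(x, band) {
  assert_ts(x)
  lo <- band[1]; hi <- band[2]
  if (!(lo > 0 && hi > lo && hi < x$fs / 2))
    stop(sprintf("band [%g, %g] Hz must lie inside (0, %g)", lo, hi, x$fs / 2))
  ord <- fir_order_3cyc(x$fs, lo)
  if (length(x$samples) < 3L * ord)
    stop(sprintf(
      "signal too short (%d samples) for FIR order %d on band [%g, %g] Hz",
      length(x$samples), ord, lo, hi))
  b <- signal::fir1(ord, c(lo, hi) / (x$fs / 2), type = "pass")
  pac_ts(fir_zerophase(x$samples, b), x$fs)
}

#' Zero-phase Butterworth band-pass extraction of a low-frequency oscillation
#'
#' 4th-order Butterworth band-pass at `f_P` with bandwidth `delta_f_P`,
#' applied forward-backward (zero phase shift).
#'
#' @param x a [pac_ts()].
#' @param f_P centre frequency in Hz.
#' @param delta_f_P bandwidth in Hz; the pass band is
#'   `f_P +/- delta_f_P / 2`.
#' @return a filtered [pac_ts()].
#' @export
extract_low_freq <- function(x, f_P, delta_f_P = 1) {
  assert_ts(x)
  lo <- f_P - delta_f_P / 2
  hi <- f_P + delta_f_P / 2
  if (!(lo > 0 && hi < x$fs / 2))
    stop(sprintf("band [%g, %g] Hz outside (0, %g)", lo, hi, x$fs / 2))
  bf <- signal::butter(4, c(lo, hi) / (x$fs / 2), type = "pass")
  y <- signal::filtfilt(bf, x$samples)
  if (anyNA(y) || !all(is.finite(y)))
    stop(sprintf("unstable Butterworth design for band [%g, %g] Hz", lo, hi))
  pac_ts(y, x$fs)
}
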