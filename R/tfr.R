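# Morlet-wavelet energy density maps, edge trimming, and the wavelet's
# frequency-domain resolution used by the labeling heuristic.

#' Morlet-wavelet energy density map
#'
#' Continuous wavelet transform with Morlet wavelets of wavenumber `w`:
#' for each analysis frequency `f` the signal is correlated with a complex
#' exponential under a Gaussian envelope of SD `w / (2 pi f)` seconds, and
#' the squared modulus is scaled by the `sqrt(2 sqrt(pi) f / w)` prefactor.
#' Computed by FFT convolution with zero padding.
#'
#' @param x a [pac_ts()].
#' @param f_A vector of analysis frequencies (Hz), all below Nyquist.
#' @param w wavenumber (unitless; values of 5 or more recommended).
#' @return object of class `pac_tfmap`: list with `energy` (time x
#'   frequency matrix, amplitude^2 units), `times` (s), `freqs` (Hz), `w`,
#'   `fs` and `i0` (number of samples trimmed from the start, 0 here).
#' @export
morlet_energy <- function(x, f_A, w = 5) {
  assert_ts(x)
  if (any(f_A >= x$fs / 2))
    stop(sprintf("f_A must be below Nyquist (%g Hz)", x$fs / 2))
  stopifnot(all(f_A > 0), w > 0)
  s <- x$samples
  n <- length(s)
  dt <- 1 / x$fs
  max_half <- ceiling(5 * w / (2 * pi * min(f_A)) * x$fs)
  nfft <- next_fast_n(n + 2L * max_half + 1L)
  S <- stats::fft(c(s, numeric(nfft - n)))
  E <- matrix(0, n, length(f_A))
  for (k in seq_along(f_A)) {
    f <- f_A[k]
    half <- ceiling(5 * w / (2 * pi * f) * x$fs)
    v <- (-half:half) * dt
    kern <- exp(-0.5 * ((2 * pi * f * v) / w)^2) * exp(1i * 2 * pi * f * v)
    # correlation: y(t) = sum_v s(t + v) kern(v) dt  ==  conv(s, Conj(kern))
    K <- stats::fft(c(Conj(kern), numeric(nfft - length(kern))))
    conv <- stats::fft(S * K, inverse = TRUE) / nfft
    y <- conv[(half + 1):(half + n)]
    E[, k] <- sqrt(2 * sqrt(pi) * f / w) * (dt * Mod(y))^2
  }
  structure(list(energy = E, times = (0:(n - 1)) * dt, freqs = f_A, w = w,
                 fs = x$fs, i0 = 0L),
            class = "pac_tfmap")
}

#' Trim wavelet edge effects from a time-frequency map
#'
#' Removes `w / min(freqs)` seconds from each end of the time axis, the
#' interval over which the wavelet support at the lowest analysis frequency
#' is distorted by the signal edges.
#'
#' @param m a `pac_tfmap` from [morlet_energy()].
#' @return a `pac_tfmap` with a shortened, contiguous time axis.
#' @export
trim_edges <- function(m) {
  stopifnot(inherits(m, "pac_tfmap"))
  n_trim <- round(m$fs * m$w / min(m$freqs))
  nt <- nrow(m$energy)
  if (2 * n_trim >= nt)
    stop(sprintf("map too short to trim %d samples from each end", n_trim))
  keep <- (n_trim + 1):(nt - n_trim)
  m$energy <- m$energy[keep, , drop = FALSE]
  m$times <- m$times[keep]
  m$i0 <- m$i0 + n_trim
  m
}

#' Frequency-domain FWHM of the Morlet wavelet
#'
#' The Gaussian envelope has time-domain SD `w / (2 pi f)`, hence
#' frequency-domain SD `f / w` and full width at half maximum
#' `2 sqrt(2 log 2) f / w`. This is the frequency resolution entering the
#' Reliable/Ambiguous congruence test.
#'
#' @param f frequency in Hz (positive).
#' @param w wavenumber (positive).
#' @return FWHM in Hz.
#' @export
wavelet_fwhm_freq <- function(f, w) {
  stopifnot(all(f > 0), w > 0)
  2 * sqrt(2 * log(2)) * f / w
}
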