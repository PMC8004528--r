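# Shared numeric helpers: analytic signal, Welch PSD, windows, peak
# prominence, seed streams. These are the low-level primitives the rest of
# the package builds on.

#' Analytic signal via the frequency domain
#'
#' Returns the complex analytic signal whose modulus is the instantaneous
#' amplitude envelope and whose argument is the instantaneous phase.
#'
#' @param x numeric vector (a real, typically band-limited, signal).
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# analytic signal of every column of a matrix in one FFT batch
analytic_mat <- function(x) {
  n <- nrow(x)
  X <- stats::mvfft(x)
  h <- numeric(n)
  if (n %% 2 == 0) { h[c(1, n / 2 + 1)] <- 1; h[2:(n / 2)] <- 2 }
  else { h[1] <- 1; h[2:((n + 1) / 2)] <- 2 }
  stats::mvfft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase and amplitude of a band-limited signal
#'
#' @param x a [pac_ts()] object, already band-pass filtered.
#' @return list of class `pac_phase_amp` with `phase` (radians in
#'   `[-pi, pi]`), `amplitude` (non-negative envelope) and `fs`.
#' @export
analytic_phase_amp <- function(x) {
  assert_ts(x)
  a <- analytic_signal(x$samples)
  structure(list(phase = Arg(a), amplitude = Mod(a), fs = x$fs),
            class = "pac_phase_amp")
}

# next size with small prime factors, for fast FFTs
next_fast_n <- function(n) {
  n <- as.integer(n)
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L, 7L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

# 4-term Blackman-Harris window (symmetric)
blackman_harris_window <- function(n) {
  if (n == 1) return(1)
  k <- 2 * pi * (0:(n - 1)) / (n - 1)
  0.35875 - 0.48829 * cos(k) + 0.14128 * cos(2 * k) - 0.01168 * cos(3 * k)
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodograms with Hann window, 50% overlap and
#' per-segment constant detrend.
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param seg_len segment length in samples (capped at `length(x)`).
#' @param overlap fractional overlap between segments (default 0.5).
#' @return list with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, seg_len = min(length(x), round(2 * fs)),
                      overlap = 0.5) {
  n <- length(x)
  seg_len <- min(as.integer(seg_len), n)
  step <- max(1L, as.integer(round(seg_len * (1 - overlap))))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- hann_window(seg_len)
  scale <- fs * sum(w^2)
  nf <- seg_len %/% 2 + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- (seg - mean(seg)) * w
    S <- Mod(stats::fft(seg))^2 / scale
    p <- S[1:nf]
    # fold the negative-frequency half into one-sided density
    if (seg_len %% 2 == 0) p[2:(nf - 1)] <- 2 * p[2:(nf - 1)]
    else p[2:nf] <- 2 * p[2:nf]
    acc <- acc + p
  }
  list(freq = (0:(nf - 1)) * fs / seg_len, psd = acc / length(starts))
}

# Single Blackman-Harris periodogram (one-sided, power per Hz)
bh_periodogram <- function(x, fs) {
  n <- length(x)
  w <- blackman_harris_window(n)
  scale <- fs * sum(w^2)
  nf <- n %/% 2 + 1L
  S <- Mod(stats::fft((x - mean(x)) * w))^2 / scale
  p <- S[1:nf]
  if (n %% 2 == 0) p[2:(nf - 1)] <- 2 * p[2:(nf - 1)] else p[2:nf] <- 2 * p[2:nf]
  list(freq = (0:(nf - 1)) * fs / n, psd = p)
}

#' Local maxima with topographic prominence
#'
#' Finds strict interior local maxima of a vector and computes each one's
#' topographic prominence: its height above the higher of the two key
#' saddles (the minima separating it from the nearest higher ground on each
#' side, or from the signal end where no higher ground exists).
#'
#' @param x numeric vector.
#' @return data.frame with columns `index`, `value`, `prominence`.
#' @export
find_peaks_prominence <- function(x) {
  n <- length(x)
  if (n < 3)
    return(data.frame(index = integer(), value = numeric(),
                      prominence = numeric()))
  d <- diff(x)
  idx <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  # keep only strict maxima (plateau right edge collapses to first sample)
  idx <- idx[x[idx] > x[pmin(idx + 1L, n)] | idx == n - 1L & x[idx] > x[n]]
  idx <- idx[x[idx] > x[idx - 1L]]
  if (!length(idx))
    return(data.frame(index = integer(), value = numeric(),
                      prominence = numeric()))
  prom <- vapply(idx, function(i) {
    v <- x[i]
    left <- x[seq_len(i - 1L)]
    hi <- which(left > v)
    lmin <- if (length(hi)) min(left[(max(hi) + 1L):(i - 1L)]) else min(left)
    right <- x[(i + 1L):n]
    hi <- which(right > v)
    rmin <- if (length(hi)) min(right[seq_len(min(hi) - 1L)]) else min(right)
    v - max(lmin, rmin)
  }, numeric(1))
  data.frame(index = idx, value = x[idx], prominence = prom)
}

#' Derive independent child seeds from a master seed
#'
#' All randomised routines consume one master seed and split it into child
#' seeds, one per independent stream, so that ensembles are reproducible and
#' insensitive to evaluation order.
#'
#' @param seed master seed (integer).
#' @param n number of child seeds.
#' @return integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @export
child_seeds <- function(seed, n) {
  stopifnot(n >= 0)
  if (n == 0) return(integer())
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# percentile rule used throughout: linear interpolation between order
# statistics (stats::quantile type 7)
pctile <- function(x, p) unname(stats::quantile(x, p / 100, type = 7, names = FALSE))
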