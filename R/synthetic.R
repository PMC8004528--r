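# Synthetic signal models used to validate PAC estimators: genuine coupling
# (phase-locked Gabor bursts, amplitude modulation, multimodal modulation),
# no-coupling controls (random bursts, narrowband filtered noise) and
# waveform-dependent "spurious" coupling (Gaussian spike trains on a 1/f
# background). Every generator is a pure function of (parameters, seed).

#' Parameters of the oscillatory-burst models
#'
#' @param f_P low (phase) frequency in Hz.
#' @param f_A high (amplitude) frequency in Hz.
#' @param amplitudes_ratio peak amplitude of the high-frequency bursts
#'   relative to the unit-amplitude low-frequency sine.
#' @param noise_level SD of the additive Gaussian white noise, relative to
#'   the low-frequency amplitude.
#' @param duration signal length in seconds.
#' @param filling fraction of low-frequency cycles carrying a burst, in
#'   `[0, 1]`.
#' @param gabor_sigma SD (seconds) of the Gaussian envelope of each burst.
#' @param burst_phase phase of the low-frequency sine (radians, with the
#'   sine written as `sin(2 pi f_P t)`) at which bursts are centred; the
#'   default `pi/2` places them on the low-frequency peaks.
#' @param fs sampling rate in Hz.
#' @return a list of class `burst_params`.
#' @export
burst_params <- function(f_P = 6, f_A = 77, amplitudes_ratio = 0.1,
                         noise_level = 0.1, duration = 10, filling = 1,
                         gabor_sigma = 0.01, burst_phase = pi / 2, fs = 512) {
  stopifnot(filling >= 0, filling <= 1, amplitudes_ratio >= 0,
            noise_level >= 0, duration > 0, fs > 0, gabor_sigma > 0)
  structure(list(f_P = f_P, f_A = f_A, amplitudes_ratio = amplitudes_ratio,
                 noise_level = noise_level, duration = duration,
                 filling = filling, gabor_sigma = gabor_sigma,
                 burst_phase = burst_phase, fs = fs),
            class = "burst_params")
}

# centres (seconds) of the low-frequency cycles' burst phase within [0, T)
burst_cycle_centers <- function(p) {
  t0 <- (p$burst_phase %% (2 * pi)) / (2 * pi * p$f_P)
  k_max <- floor((p$duration - t0) * p$f_P)
  if (k_max < 0) return(numeric())
  t0 + (0:k_max) / p$f_P
}

add_gabors <- function(t, centers, amp, sigma, f_A) {
  x <- numeric(length(t))
  for (tc in centers)
    x <- x + amp * exp(-((t - tc)^2) / (2 * sigma^2)) * cos(2 * pi * f_A * (t - tc))
  x
}

#' Coupled oscillatory bursts
#'
#' A unit-amplitude low-frequency sine with Gabor bursts of the high
#' frequency superimposed at a fixed phase of (a random subset of) its
#' cycles, plus Gaussian white noise. Bursts running past the signal end are
#' truncated.
#'
#' @param params a [burst_params()] list.
#' @param seed integer seed.
#' @return a [pac_ts()].
#' @export
gen_coupled_bursts <- function(params = burst_params(), seed = 1) {
  p <- params
  n <- round(p$duration * p$fs)
  t <- (0:(n - 1)) / p$fs
  centers <- burst_cycle_centers(p)
  with_seed(seed, {
    if (p$filling < 1 && length(centers)) {
      keep <- sample.int(length(centers), round(p$filling * length(centers)))
      centers <- sort(centers[keep])
    }
    x <- sin(2 * pi * p$f_P * t) +
      add_gabors(t, centers, p$amplitudes_ratio, p$gabor_sigma, p$f_A) +
      p$noise_level * stats::rnorm(n)
    pac_ts(x, p$fs)
  })
}

#' Random oscillatory bursts (no-coupling control)
#'
#' Same construction as [gen_coupled_bursts()] but with burst centres drawn
#' uniformly over the signal duration, independent of the low-frequency
#' phase. The number of bursts matches the coupled model's cycle count.
#'
#' @inheritParams gen_coupled_bursts
#' @return a [pac_ts()].
#' @export
gen_random_bursts <- function(params = burst_params(), seed = 1) {
  p <- params
  n <- round(p$duration * p$fs)
  t <- (0:(n - 1)) / p$fs
  n_bursts <- length(burst_cycle_centers(p))
  if (p$filling < 1) n_bursts <- round(p$filling * n_bursts)
  with_seed(seed, {
    centers <- sort(stats::runif(n_bursts, 0, p$duration))
    x <- sin(2 * pi * p$f_P * t) +
      add_gabors(t, centers, p$amplitudes_ratio, p$gabor_sigma, p$f_A) +
      p$noise_level * stats::rnorm(n)
    pac_ts(x, p$fs)
  })
}

#' Parameters of the amplitude-modulation models
#'
#' @param chi fraction of the high-frequency amplitude that is *not*
#'   modulated, in `[0, 1]`; the depth of modulation is `1 - chi`.
#' @param A_fA_bar maximal amplitude of the high-frequency oscillation.
#' @param A_fP_bar amplitude of the low-frequency sine.
#' @param A_N_bar amplitude of the additive white noise, in `[0, 1]`.
#' @inheritParams burst_params
#' @return a list of class `am_params`.
#' @export
am_params <- function(chi = 0.1, A_fA_bar = 0.1, A_fP_bar = 1, A_N_bar = 0.1,
                      f_P = 6, f_A = 77, fs = 512, duration = 10) {
  if (chi < 0 || chi > 1) stop("`chi` must lie in [0, 1]")
  stopifnot(A_fA_bar >= 0, A_N_bar >= 0, duration > 0, fs > 0)
  structure(list(chi = chi, A_fA_bar = A_fA_bar, A_fP_bar = A_fP_bar,
                 A_N_bar = A_N_bar, f_P = f_P, f_A = f_A, fs = fs,
                 duration = duration),
            class = "am_params")
}

#' Sinusoid with sinusoidally modulated high-frequency amplitude
#'
#' The high-frequency amplitude follows
#' `A(t) = A_fA_bar * ((1 - chi) sin(2 pi f_P t) + 1 + chi) / 2`, riding on
#' a low-frequency sine plus white noise.
#'
#' @param params an [am_params()] list.
#' @param seed integer seed.
#' @return a [pac_ts()].
#' @export
gen_amplitude_modulated <- function(params = am_params(), seed = 1) {
  p <- params
  n <- round(p$duration * p$fs)
  t <- (0:(n - 1)) / p$fs
  A <- p$A_fA_bar * ((1 - p$chi) * sin(2 * pi * p$f_P * t) + 1 + p$chi) / 2
  with_seed(seed, {
    x <- A * sin(2 * pi * p$f_A * t) + p$A_fP_bar * sin(2 * pi * p$f_P * t) +
      p$A_N_bar * stats::rnorm(n)
    pac_ts(x, p$fs)
  })
}

#' Parameters of the multimodal coupling model
#'
#' @param n_modes number of phase modes (1, 2 or 3 in the validation suite).
#' @param mode_phases low-frequency phases (radians, analytic-phase
#'   convention) at which the high-frequency amplitude is augmented.
#' @param gaussian_variance variance of the Gaussian bump applied to the
#'   sawtooth wave.
#' @inheritParams am_params
#' @return a list of class `multimodal_params`.
#' @export
multimodal_params <- function(n_modes = 1,
                              mode_phases = c(4 * pi / 5, 3 * pi / 2, pi / 10),
                              gaussian_variance = 0.1, chi = 0.1,
                              A_fA_bar = 0.1, A_fP_bar = 1, A_N_bar = 0.1,
                              f_P = 6, f_A = 77, fs = 512, duration = 10) {
  stopifnot(n_modes >= 1, length(mode_phases) >= n_modes)
  structure(list(n_modes = n_modes, mode_phases = mode_phases[seq_len(n_modes)],
                 gaussian_variance = gaussian_variance, chi = chi,
                 A_fA_bar = A_fA_bar, A_fP_bar = A_fP_bar, A_N_bar = A_N_bar,
                 f_P = f_P, f_A = f_A, fs = fs, duration = duration),
            class = "multimodal_params")
}

# sawtooth in [-1, 1) that crosses 0 (rising) at psi = 0 mod 2*pi
sawtooth_centered <- function(psi) 2 * ((psi / (2 * pi) + 0.5) %% 1) - 1

# one normalized modulation mode: Gaussian bump of the lagged sawtooth,
# min-max scaled to [0, 1]. The sawtooth is expressed on a phase scale
# (radians, [-pi, pi)), so the Gaussian's variance is in rad^2 and the bump
# is narrow enough for neighbouring modes to stay distinct.
mode_envelope <- function(f_P, t, phase, variance) {
  # analytic phase of sin(2 pi f t) is 2 pi f t - pi/2
  sw <- pi * sawtooth_centered(2 * pi * f_P * t - pi / 2 - phase)
  g <- stats::dnorm(sw, 0, sqrt(variance))
  (g - min(g)) / (max(g) - min(g))
}

#' High-frequency sine coupled to multiple low-frequency phases
#'
#' The high-frequency amplitude is a sum of Gaussian bumps of lagged
#' sawtooth waves, one per mode, each min-max normalised to `[0, 1]`; the
#' carrier, low-frequency sine and noise enter as in
#' [gen_amplitude_modulated()].
#'
#' @param params a [multimodal_params()] list.
#' @param seed integer seed.
#' @return a [pac_ts()].
#' @export
gen_multimodal <- function(params = multimodal_params(), seed = 1) {
  p <- params
  n <- round(p$duration * p$fs)
  t <- (0:(n - 1)) / p$fs
  g <- rowSums(vapply(p$mode_phases,
                      function(ph) mode_envelope(p$f_P, t, ph,
                                                 p$gaussian_variance),
                      numeric(n)))
  A <- p$A_fA_bar * ((1 - p$chi) * g + p$chi)
  with_seed(seed, {
    x <- A * sin(2 * pi * p$f_A * t) + p$A_fP_bar * sin(2 * pi * p$f_P * t) +
      p$A_N_bar * stats::rnorm(n)
    pac_ts(x, p$fs)
  })
}

#' Narrowband filtered noise (no-coupling control)
#'
#' A 6 Hz unit sine plus Gaussian white noise band-passed to `[76, 78]` Hz
#' (Butterworth, 2nd order) and rescaled so its maximum absolute value is
#' 0.1, embedded in white noise.
#'
#' @param noise_level SD of the additive white noise.
#' @param duration signal length in seconds.
#' @param fs sampling rate in Hz.
#' @param seed integer seed.
#' @return a [pac_ts()].
#' @export
gen_filtered_noise_hf <- function(noise_level = 0.1, duration = 10, fs = 512,
                                  seed = 1) {
  if (duration <= 0) stop("`duration` must be positive")
  n <- round(duration * fs)
  t <- (0:(n - 1)) / fs
  bf <- signal::butter(2, c(76, 78) / (fs / 2), type = "pass")
  with_seed(seed, {
    hf <- signal::filtfilt(bf, stats::rnorm(n))
    hf <- hf / max(abs(hf)) * 0.1
    pac_ts(sin(2 * pi * 6 * t) + hf + noise_level * stats::rnorm(n), fs)
  })
}

#' Parameters of the Gaussian spike-train models
#'
#' @param periodic logical; `TRUE` for jittered-periodic event times,
#'   `FALSE` for uniformly random ones.
#' @param mean_interval mean inter-spike interval in seconds (periodic case).
#' @param interval_jitter half-width of the uniform interval jitter (s).
#' @param n_events number of events (non-periodic case).
#' @param fwhm full width at half maximum of each Gaussian spike (s).
#' @param amplitude_sd spike amplitude as a multiple of the background SD.
#' @param fs sampling rate in Hz.
#' @param duration length of the extracted fragment in seconds.
#' @return a list of class `gaussian_train_params`.
#' @export
gaussian_train_params <- function(periodic = TRUE, mean_interval = 0.1,
                                  interval_jitter = 0.02, n_events = 100,
                                  fwhm = 0.015, amplitude_sd = 5, fs = 1000,
                                  duration = 10) {
  stopifnot(fwhm > 0, amplitude_sd > 0, mean_interval > 0, duration > 0)
  structure(list(periodic = periodic, mean_interval = mean_interval,
                 interval_jitter = interval_jitter, n_events = n_events,
                 fwhm = fwhm, amplitude_sd = amplitude_sd, fs = fs,
                 duration = duration),
            class = "gaussian_train_params")
}

#' Train of Gaussian spikes on a background signal
#'
#' Places Gaussian spikes (default FWHM 15 ms, amplitude a multiple of the
#' background SD) at jittered-periodic or uniformly random times on the
#' supplied background, applies zero-phase high-pass (1 Hz) and low-pass
#' (250 Hz) Butterworth (2nd order) filters, and returns the central
#' `duration`-second fragment. The background stands in for PAC-free EEG; a
#' unit-SD [gen_pink_noise()] realisation is the intended default.
#'
#' @param params a [gaussian_train_params()] list.
#' @param background a [pac_ts()] with `fs == params$fs` and duration at
#'   least `params$duration`.
#' @param seed integer seed.
#' @return a [pac_ts()] of `params$duration` seconds.
#' @export
gen_gaussian_train <- function(params = gaussian_train_params(),
                               background, seed = 1) {
  p <- params
  assert_ts(background)
  if (background$fs != p$fs) stop("background `fs` must equal params$fs")
  if (background$duration < p$duration)
    stop("background shorter than the requested duration")
  n <- length(background$samples)
  T_bg <- n / p$fs
  t <- (0:(n - 1)) / p$fs
  sigma <- p$fwhm / (2 * sqrt(2 * log(2)))
  amp <- p$amplitude_sd * stats::sd(background$samples)
  with_seed(seed, {
    times <- if (p$periodic) {
      iv <- stats::runif(ceiling(T_bg / (p$mean_interval - p$interval_jitter)) + 1,
                         p$mean_interval - p$interval_jitter,
                         p$mean_interval + p$interval_jitter)
      tt <- stats::runif(1, 0, p$mean_interval) + cumsum(c(0, iv))
      tt[tt < T_bg]
    } else {
      sort(round(stats::runif(p$n_events, 0, T_bg) * 1000) / 1000)
    }
    spikes <- numeric(n)
    half <- ceiling(5 * sigma * p$fs)
    for (tc in times) {
      ic <- round(tc * p$fs) + 1
      sel <- max(1, ic - half):min(n, ic + half)
      spikes[sel] <- spikes[sel] + amp * exp(-((t[sel] - tc)^2) / (2 * sigma^2))
    }
    x <- background$samples + spikes
    x <- signal::filtfilt(signal::butter(2, 1 / (p$fs / 2), type = "high"), x)
    x <- signal::filtfilt(signal::butter(2, 250 / (p$fs / 2), type = "low"), x)
    n_out <- round(p$duration * p$fs)
    start <- max(1, floor((n - n_out) / 2) + 1)
    pac_ts(x[start:(start + n_out - 1)], p$fs)
  })
}

#' Pink (1/f) noise
#'
#' Spectrally shaped Gaussian white noise: the white spectrum is multiplied
#' by a `1/sqrt(f)` amplitude mask and transformed back, giving a power
#' spectral density proportional to `1/f`. The output is zero-mean with unit
#' SD.
#'
#' @param n_samples number of samples (positive).
#' @param fs sampling rate in Hz.
#' @param seed integer seed.
#' @return a [pac_ts()].
#' @export
gen_pink_noise <- function(n_samples, fs, seed = 1) {
  n <- as.integer(n_samples)
  if (n <= 0) stop("`n_samples` must be positive")
  with_seed(seed, {
    W <- stats::fft(stats::rnorm(n))
    f_idx <- c(0, pmin(1:(n - 1), n - (1:(n - 1))))  # symmetric bin index
    mask <- c(0, 1 / sqrt(f_idx[-1]))
    x <- Re(stats::fft(W * mask, inverse = TRUE) / n)
    x <- (x - mean(x)) / stats::sd(x)
    pac_ts(x, fs)
  })
}
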