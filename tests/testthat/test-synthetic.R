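# Synthetic signal models: construction identities, burst counts against a
# zero-crossing oracle, envelope laws, spectral content, determinism.

test_that("coupled-bursts generator matches its construction", {
  x <- gen_coupled_bursts(burst_params(), seed = 1)
  expect_equal(length(x$samples), 5120)
  expect_equal(x$fs, 512)

  # amplitudes_ratio = 0, noise = 0 -> pure unit sine
  p0 <- burst_params(amplitudes_ratio = 0, noise_level = 0)
  x0 <- gen_coupled_bursts(p0, seed = 1)
  expect_equal(max(abs(x0$samples)), 1, tolerance = 1e-6)
  t <- ts_time(x0)
  expect_equal(x0$samples, sin(2 * pi * 6 * t), tolerance = 1e-12)

  # filling = 1, noise = 0 -> one burst per complete cycle (zero-crossing
  # oracle); bursts visible as local energy at 77 Hz
  pc <- burst_params(noise_level = 0)
  xc <- gen_coupled_bursts(pc, seed = 2)
  resid <- xc$samples - sin(2 * pi * 6 * t)
  # count bursts as threshold crossings of the residual's Hilbert envelope
  env <- Mod(analytic_signal(resid))
  runs <- rle(env > 0.5 * max(env))
  n_bursts <- sum(runs$values)
  expect_equal(n_bursts, cycle_count_zero_cross(6, 10, 512), tolerance = 1)
})

test_that("partial filling yields a proportional burst count", {
  for (fill in c(0.2, 0.5, 0.8)) {
    p <- burst_params(noise_level = 0, filling = fill)
    x <- gen_coupled_bursts(p, seed = 5)
    env <- Mod(analytic_signal(x$samples - sin(2 * pi * 6 * ts_time(x))))
    runs <- rle(env > 0.5 * max(env))
    expect_equal(sum(runs$values), round(fill * 60), tolerance = 1)
  }
})

test_that("amplitude-modulation model follows its envelope law", {
  # chi = 1 -> constant envelope
  x1 <- gen_amplitude_modulated(am_params(chi = 1, A_N_bar = 0, A_fP_bar = 0),
                                seed = 1)
  env <- Mod(analytic_signal(x1$samples))
  mid <- 500:4600
  expect_lt(max(abs(env[mid] - 0.1)), 0.002)

  # chi = 0 -> envelope spans [0, A_fA_bar]
  x0 <- gen_amplitude_modulated(am_params(chi = 0, A_N_bar = 0, A_fP_bar = 0),
                                seed = 1)
  env0 <- Mod(analytic_signal(x0$samples))
  expect_lt(min(env0[mid]), 0.004)
  expect_equal(max(env0[mid]), 0.1, tolerance = 0.01)

  # chi = 0.1 -> envelope min/max ratio = chi (Hilbert-envelope oracle)
  xd <- gen_amplitude_modulated(am_params(A_N_bar = 0, A_fP_bar = 0), seed = 1)
  envd <- Mod(analytic_signal(xd$samples))[mid]
  expect_equal(min(envd) / max(envd), 0.1, tolerance = 0.02)

  # invalid chi rejected
  expect_error(am_params(chi = 1.2), "chi")
})

test_that("AM envelope identity holds to < 2% relative RMS away from edges", {
  p <- am_params(A_N_bar = 0, A_fP_bar = 0)
  x <- gen_amplitude_modulated(p, seed = 3)
  t <- ts_time(x)
  expected <- p$A_fA_bar * ((1 - p$chi) * sin(2 * pi * 6 * t) + 1 + p$chi) / 2
  env <- Mod(analytic_signal(x$samples))
  mid <- 500:4600
  rel_rms <- sqrt(mean((env[mid] - expected[mid])^2)) /
    sqrt(mean(expected[mid]^2))
  expect_lt(rel_rms, 0.02)
})

test_that("multimodal modes are normalized and produce the right mode count", {
  # each mode envelope is min-max normalized to [0, 1]
  t <- (0:5119) / 512
  g <- emipac:::mode_envelope(6, t, 4 * pi / 5, 0.1)
  expect_equal(min(g), 0)
  expect_equal(max(g), 1)

  # histogram of the noiseless envelope over phase bins: 1 mode -> single
  # local maximum, 3 modes -> three (brute-force binning oracle)
  count_modes <- function(n_modes) {
    p <- multimodal_params(n_modes = n_modes, A_N_bar = 0, A_fP_bar = 0)
    x <- gen_multimodal(p, seed = 1)
    env <- Mod(analytic_signal(x$samples))
    phase <- (2 * pi * 6 * t - pi / 2 + pi) %% (2 * pi) - pi
    bins <- pmin(floor((phase + pi) / (2 * pi) * 18) + 1, 18)
    h <- tapply(env, bins, mean)
    up <- h > h[c(18, 1:17)] & h > h[c(2:18, 1)]  # circular local maxima
    sum(up & h > min(h) + 0.25 * (max(h) - min(h)))  # ignore baseline ripple
  }
  expect_equal(count_modes(1), 1)
  expect_equal(count_modes(3), 3)
})

test_that("filtered-noise control has the prescribed components", {
  x <- gen_filtered_noise_hf(noise_level = 0, seed = 4)
  # high-frequency component rescaled so its maximum is exactly 0.1
  hf <- x$samples - sin(2 * pi * 6 * ts_time(x))
  expect_equal(max(abs(hf)), 0.1, tolerance = 1e-9)
  # spectrum concentrated near 6 Hz and 76-78 Hz (periodogram oracle)
  ps <- welch_psd(x$samples, 512, seg_len = 2048)
  top <- order(ps$psd, decreasing = TRUE)[1:12]
  f_top <- ps$freq[top]
  expect_true(all(abs(f_top - 6) < 1.5 | (f_top > 70 & f_top < 84)))
  expect_error(gen_filtered_noise_hf(duration = 0), "duration")
})

test_that("Gaussian-train generator places and shapes spikes as specified", {
  bg <- gen_pink_noise(12000, 1000, seed = 8)
  p <- gaussian_train_params(amplitude_sd = 5)
  x <- gen_gaussian_train(p, bg, seed = 9)
  expect_equal(length(x$samples), 10000)
  # about duration / mean_interval spikes in 10 s
  th <- 2.5 * sd(bg$samples)
  runs <- rle(x$samples > th)
  expect_gt(sum(runs$values), 80)
  expect_lt(sum(runs$values), 120)
  # FWHM -> sigma conversion
  sigma <- p$fwhm / (2 * sqrt(2 * log(2)))
  expect_equal(sigma, 0.015 / 2.3548, tolerance = 1e-3)
  expect_error(gen_gaussian_train(p, gen_pink_noise(500, 1000, 1), 1),
               "shorter")
})

test_that("pink noise has 1/f spectrum and zero mean", {
  # log-log slope of the averaged periodogram over 1-100 Hz (regression
  # oracle over many realizations)
  acc <- NULL
  for (s in 1:40) {
    x <- gen_pink_noise(5120, 512, seed = s)
    ps <- welch_psd(x$samples, 512, seg_len = 1024)
    acc <- if (is.null(acc)) ps$psd else acc + ps$psd
  }
  sel <- ps$freq >= 1 & ps$freq <= 100
  fit <- lm(log10(acc[sel]) ~ log10(ps$freq[sel]))
  expect_equal(unname(coef(fit)[2]), -1, tolerance = 0.1)
  x <- gen_pink_noise(10000, 500, seed = 1)
  expect_lt(abs(mean(x$samples)), 3 / sqrt(10000))
  expect_error(gen_pink_noise(0, 100), "positive")
})

test_that("every generator is a pure function of (params, seed)", {
  gens <- list(
    function(s) gen_coupled_bursts(burst_params(filling = 0.5), s),
    function(s) gen_random_bursts(burst_params(), s),
    function(s) gen_amplitude_modulated(am_params(), s),
    function(s) gen_multimodal(multimodal_params(n_modes = 2), s),
    function(s) gen_filtered_noise_hf(0.1, seed = s),
    function(s) gen_pink_noise(2048, 512, s)
  )
  for (g in gens) {
    expect_identical(g(11)$samples, g(11)$samples)
    expect_false(identical(g(11)$samples, g(12)$samples))
  }
})

test_that("random-burst phases are uniform over the slow cycle", {
  # circular resultant of burst-centre phases shrinks for long signals
  p <- burst_params(noise_level = 0, duration = 40)
  x <- gen_random_bursts(p, seed = 21)
  resid <- Mod(analytic_signal(x$samples - sin(2 * pi * 6 * ts_time(x))))
  th <- 0.5 * max(resid)
  r <- rle(resid > th)
  ends <- cumsum(r$lengths)
  centers <- (ends[r$values] + ends[r$values] - r$lengths[r$values]) / 2
  phases <- 2 * pi * 6 * (centers / 512) %% (2 * pi)
  resultant <- Mod(mean(exp(1i * phases)))
  expect_lt(resultant, 0.2)
})
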