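# Reference estimators: filtering behaviour, analytic phase/amplitude,
# dPAC and MI identities, naive-loop oracles, invariances, comodulogram
# localization and surrogate contracts.

test_that("zero-phase FIR band-pass preserves in-band and rejects out-of-band", {
  fs <- 512
  t <- (0:(10 * fs - 1)) / fs
  x <- pac_ts(sin(2 * pi * 20 * t), fs)
  y <- fir_bandpass_two_way(x, c(15, 25))
  mid <- 1000:4000
  env <- Mod(analytic_signal(y$samples))[mid]
  expect_lt(max(abs(env - 1)), 0.05)

  # one octave below the band: attenuated by > 20 dB
  x2 <- pac_ts(sin(2 * pi * 7.5 * t), fs)
  y2 <- fir_bandpass_two_way(x2, c(15, 25))
  expect_lt(20 * log10(max(Mod(analytic_signal(y2$samples))[mid])), -20)

  # zero input -> zero output; short signal -> error
  expect_equal(fir_bandpass_two_way(pac_ts(numeric(5120) + 0, fs),
                                    c(15, 25))$samples,
               numeric(5120))
  expect_error(fir_bandpass_two_way(pac_ts(rnorm(100), fs), c(2, 3)),
               "too short")
  expect_error(fir_bandpass_two_way(x, c(200, 300)), "band")
})

test_that("analytic signal yields correct instantaneous phase and amplitude", {
  fs <- 512
  t <- (0:(4 * fs - 1)) / fs
  pa <- analytic_phase_amp(pac_ts(cos(2 * pi * 6 * t), fs))
  mid <- 200:1800
  # unwrapped phase advances at 2*pi*6 rad/s
  dphi <- diff(pa$phase[mid])
  dphi <- (dphi + pi) %% (2 * pi) - pi
  expect_equal(mean(dphi) * fs, 2 * pi * 6, tolerance = 1e-6)
  expect_lt(max(abs(pa$amplitude[mid] - 1)), 0.01)

  # amplitude scales with the signal
  pa3 <- analytic_phase_amp(pac_ts(3 * cos(2 * pi * 6 * t), fs))
  expect_equal(mean(pa3$amplitude[mid]), 3, tolerance = 0.01)

  # chirp: instantaneous frequency tracks the chirp law within 2%
  f0 <- 5; f1 <- 15; T_ <- 4
  phase_law <- 2 * pi * (f0 * t + (f1 - f0) / (2 * T_) * t^2)
  pa_c <- analytic_phase_amp(pac_ts(cos(phase_law), fs))
  inst_f <- ((diff(pa_c$phase) + pi) %% (2 * pi) - pi) * fs / (2 * pi)
  f_true <- f0 + (f1 - f0) / T_ * t[-1]
  sel <- 200:1800
  expect_lt(max(abs(inst_f[sel] - f_true[sel]) / f_true[sel]), 0.02)
})

test_that("dPAC satisfies its closed-form identities and the loop oracle", {
  # constant amplitude at constant phase -> exactly 1
  expect_equal(dpac(list(phase = rep(1.2, 500), amplitude = rep(2, 500))), 1)
  # uniform phase over an integer number of cycles -> 0
  ph <- seq(-pi, pi, length.out = 1001)[-1]
  expect_lt(dpac(list(phase = ph, amplitude = rep(1, 1000))), 1e-12)
  # all-zero amplitude is undefined
  expect_error(dpac(list(phase = ph, amplitude = rep(0, 1000))), "amplitude")

  # A(t) = 1 + cos(phi) over k cycles: matches direct summation oracle
  ph_k <- rep(seq(-pi, pi, length.out = 201)[-1], 5)
  A <- 1 + cos(ph_k)
  expect_equal(dpac(list(phase = ph_k, amplitude = A)),
               dpac_naive(ph_k, A), tolerance = 1e-12)
})

test_that("MI satisfies its closed-form identities and the loop oracle", {
  # uniform amplitude -> 0
  ph <- seq(-pi, pi, length.out = 1801)[-1]
  expect_equal(mi(list(phase = ph, amplitude = rep(3, 1800))), 0,
               tolerance = 1e-12)
  # all mass in one bin -> 1
  expect_equal(mi(list(phase = rep(0.1, 100), amplitude = rep(1, 100))), 1)
  # hand-computable 3-bin case
  pa <- list(phase = c(rep(-2, 4), rep(0, 4), rep(2, 4)),
             amplitude = c(rep(2, 4), rep(1, 8)))
  expect_equal(mi(pa, J = 3),
               (log(3) + 0.5 * log(0.5) + 2 * 0.25 * log(0.25)) / log(3),
               tolerance = 1e-12)
  expect_error(mi(list(phase = ph, amplitude = rep(0, 1800))), "amplitude")
})

test_that("vectorized estimators match naive loops to 1e-10 on short series", {
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(500:2000, 1)
    phase <- runif(n, -pi, pi)
    amp <- matrix(abs(rnorm(n * 3)), n, 3)
    v_mi <- emipac:::mi_cols_batch(matrix(phase), amp, 18L)
    v_dp <- emipac:::dpac_cols_batch(matrix(cos(phase)), matrix(sin(phase)),
                                     amp)
    for (j in 1:3) {
      expect_equal(v_mi[1, j], mi_naive(phase, amp[, j]), tolerance = 1e-10)
      expect_equal(v_dp[1, j], dpac_naive(phase, amp[, j]), tolerance = 1e-10)
    }
  }
})

test_that("MI and dPAC are invariant to amplitude scaling and phase shifts", {
  set.seed(3)
  phase <- runif(1200, -pi, pi)
  amp <- abs(rnorm(1200)) + 0.1
  m0 <- mi(list(phase = phase, amplitude = amp))
  d0 <- dpac(list(phase = phase, amplitude = amp))
  expect_equal(mi(list(phase = phase, amplitude = 7.3 * amp)), m0)
  expect_equal(dpac(list(phase = phase, amplitude = 7.3 * amp)), d0)
  # circular rotation by whole bins leaves MI unchanged
  rot <- ((phase + pi + 2 * (2 * pi / 18)) %% (2 * pi)) - pi
  expect_equal(mi(list(phase = rot, amplitude = amp)), m0, tolerance = 1e-12)
  # global phase offset leaves |dPAC| unchanged
  off <- ((phase + pi + 0.7) %% (2 * pi)) - pi
  expect_equal(dpac(list(phase = off, amplitude = amp)), d0, tolerance = 1e-12)
})

test_that("MI comodulogram localizes the coupled-bursts pair", {
  x <- gen_coupled_bursts(burst_params(noise_level = 0.05), seed = 31)
  g <- test_grid()
  cm <- reference_comodulogram(x, g, "mi")
  am <- which(cm$values == max(cm$values), arr.ind = TRUE)
  # frequency-for-amplitude localized within one step of 77 Hz; frequency
  # for phase spreads for the reference methods, so only f_A is pinned
  expect_lte(abs(g$f_A[am[2]] - 77), 5)
  expect_gt(cm$values[which.min(abs(g$f_P - 6)), which.min(abs(g$f_A - 77))],
            0.5 * max(cm$values))
  # determinism
  cm2 <- reference_comodulogram(x, g, "mi")
  expect_identical(cm$values, cm2$values)
  # grid exceeding Nyquist names the pair
  expect_error(reference_comodulogram(x, pac_grid(seq(2, 10, 1), c(250)),
                                      "mi"), "Nyquist")
})

test_that("reference surrogates keep the amplitude and randomize the phase", {
  x <- gen_coupled_bursts(burst_params(), seed = 11)
  g <- pac_grid(c(5, 6, 7), c(70, 77, 85))
  surr <- reference_surrogates(x, g, "mi", n_surrogates = 30, seed = 2)
  expect_length(surr, 30)
  # mean surrogate MI at the coupled pair is far below the original
  orig <- reference_comodulogram(x, g, "mi")$values[2, 2]
  s_vals <- vapply(surr, function(s) s$values[2, 2], numeric(1))
  expect_lt(mean(s_vals), orig / 3)
  # distinct seeds give distinct surrogate ensembles
  surr_b <- reference_surrogates(x, g, "mi", n_surrogates = 20, seed = 3)
  expect_false(identical(surr[[1]]$values, surr_b[[1]]$values))
})

test_that("dPAC needs more than 2 s of data", {
  x <- gen_coupled_bursts(burst_params(duration = 2), seed = 1)
  expect_error(reference_comodulogram(x, test_grid(), "dpac"), "2 s")
})
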