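# eMI pipeline components: spectral screening, low-frequency extraction,
# cycle maxima, section averaging, surrogate maps, comodulogram centering,
# phase distributions and section spectra.

test_that("screen flags a strong oscillation and passes pink noise at ~5%", {
  fs <- 512
  n <- 10 * fs
  # pink noise + strong 6 Hz sine: 6 Hz must be significant
  pk <- gen_pink_noise(n, fs, seed = 4)
  x <- pac_ts(pk$samples + 3 * sin(2 * pi * 6 * ts_time(pk)), fs)
  scr <- screen_phase_frequencies(x, seq(2, 10, 1), n_pink = 60, seed = 5)
  expect_true(scr$significant[scr$f_P == 6])

  # pure pink noise: significant fraction near the nominal 5% level
  hits <- 0; total <- 0
  for (s in 1:12) {
    y <- gen_pink_noise(n, fs, seed = 100 + s)
    sc <- screen_phase_frequencies(y, seq(2, 10, 1), n_pink = 60,
                                   seed = 200 + s)
    hits <- hits + sum(sc$significant); total <- total + length(sc$significant)
  }
  # 95% binomial band around 0.05 for 108 draws
  expect_lte(hits, qbinom(0.995, total, 0.05))
})

test_that("background ratio of a flat spectrum region is near 1", {
  ps <- welch_psd(rnorm(8192), 512, seg_len = 1024)
  bg <- emipac:::spectrum_background(ps$freq, ps$psd)
  sel <- ps$freq > 20 & ps$freq < 200
  # the background interpolates the minima envelope, so the ratio sits a
  # little above 1 for a noisy flat spectrum but stays O(1)
  r <- median(ps$psd[sel] / bg$background[sel])
  expect_gt(r, 0.8)
  expect_lt(r, 2)
})

test_that("Butterworth extraction is zero-phase and band-selective", {
  fs <- 512
  t <- (0:(10 * fs - 1)) / fs
  x <- pac_ts(sin(2 * pi * 6 * t), fs)
  y <- extract_low_freq(x, 6, 1)
  mid <- 1000:4000
  expect_lt(max(abs(y$samples[mid] - x$samples[mid])), 0.05)
  # zero phase shift: cross-correlation peak at zero lag
  cc <- ccf(y$samples[mid], x$samples[mid], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # DC is rejected (away from the filter's edge transients)
  dc <- extract_low_freq(pac_ts(rep(1, 5120), fs), 6, 1)
  expect_lt(max(abs(dc$samples[2000:3000])), 0.01)
  expect_error(extract_low_freq(x, 300, 1), "band")
})

test_that("cycle maxima of a clean sine are evenly spaced and selected", {
  fs <- 512
  t <- (0:(10 * fs - 1)) / fs
  s6 <- pac_ts(sin(2 * pi * 6 * t), fs)
  cm <- find_cycle_maxima(s6, 6)
  expect_false(cm$abandoned)
  # spacing 1/6 s
  expect_equal(median(diff(cm$times)), 1 / 6, tolerance = 0.01)
  # edge rule: no maxima within 1.5/f_P of the ends
  expect_gte(min(cm$times), 1.5 / 6)
  expect_lte(max(cm$times), 10 - 1.5 / 6)
  # path A keeps nearly all interior maxima, path B roughly every 3rd
  expect_gt(cm$n_A, 0.8 * length(cm$index))
  expect_lt(cm$n_B, 0.45 * length(cm$index))
  # windows within each selection are pairwise disjoint
  half_A <- (cm$len_A - 1) / 2
  expect_true(all(diff(cm$sel_A) > 2 * half_A))
  half_B <- (cm$len_B - 1) / 2
  expect_true(all(diff(cm$sel_B) > 2 * half_B))
})

test_that("low-prominence ripple maxima are excluded", {
  fs <- 512
  t <- (0:(10 * fs - 1)) / fs
  # sine with a tiny fast ripple creating sub-threshold local maxima
  s <- pac_ts(sin(2 * pi * 6 * t) + 0.002 * sin(2 * pi * 40 * t), fs)
  cm <- find_cycle_maxima(s, 6)
  # only one maximum per cycle survives the 5%-of-median prominence filter
  expect_lt(length(cm$index), 70)
  expect_equal(median(diff(cm$times)), 1 / 6, tolerance = 0.01)
})

test_that("too-short signals are abandoned as insufficient cycles", {
  fs <- 512
  t <- (0:(round(0.4 * fs) - 1)) / fs
  cm <- find_cycle_maxima(pac_ts(sin(2 * pi * 6 * t), fs), 6)
  expect_true(cm$abandoned)
  expect_match(cm$reason, "insufficient")
})

test_that("section averaging reproduces constants and aligns cycles", {
  fs <- 512
  t <- (0:(10 * fs - 1)) / fs
  x <- pac_ts(sin(2 * pi * 6 * t) + 0.01 * rnorm(length(t)), fs)
  s6 <- extract_low_freq(x, 6, 1)
  cm <- find_cycle_maxima(s6, 6)
  E <- trim_edges(morlet_energy(x, seq(40, 80, 10), w = 5))
  # averaging a constant map returns the constant
  Ec <- E; Ec$energy[] <- 2.5
  sec_c <- average_sections(Ec, s6, x, cm)
  expect_true(all(abs(sec_c$M_A - 2.5) < 1e-12))
  # SP_A is one aligned cycle: peak at the centre sample
  sec <- average_sections(E, s6, x, cm)
  expect_equal(which.max(sec$SP_A), (sec$len_A + 1) / 2, tolerance = 1)
  expect_equal(sec$len_A, emipac:::odd_len(fs / 6))
})

test_that("surrogate maps are reproducible and preserve energy", {
  x <- gen_coupled_bursts(burst_params(), seed = 13)
  s6 <- extract_low_freq(x, 6, 1)
  cm <- find_cycle_maxima(s6, 6)
  E <- trim_edges(morlet_energy(x, seq(40, 120, 10), w = 5))
  sec <- average_sections(E, s6, x, cm)
  su1 <- surrogate_maps(E, sec, n_surrogates = 20, seed = 9)
  su2 <- surrogate_maps(E, sec, n_surrogates = 20, seed = 9)
  expect_identical(su1$maps, su2$maps)
  su3 <- surrogate_maps(E, sec, n_surrogates = 20, seed = 10)
  expect_false(identical(su1$maps[[1]], su3$maps[[1]]))
  # grand mean energy preserved under jitter within 5%
  gm_orig <- mean(sec$M_A)
  gm_surr <- mean(vapply(su1$maps, mean, numeric(1)))
  expect_lt(abs(gm_surr - gm_orig) / gm_orig, 0.05)
})

test_that("comodulogram centering and localization behave as designed", {
  x <- gen_coupled_bursts(burst_params(noise_level = 0.05), seed = 17)
  r <- emi_pac(x, f_P = seq(4, 8, 1), f_A = seq(40, 120, 5),
               n_surrogates = 40, seed = 3)
  active <- which(r$status == "analysed")
  expect_gt(length(active), 0)
  # per-pair surrogate mean is zero after centering (direct check on a
  # freshly built surrogate array)
  cmv <- emipac:::emi_comodulogram(r$per_fp$sections,
    lapply(seq_along(r$grid$f_P), function(i)
      if (is.null(r$per_fp$sections[[i]])) NULL
      else surrogate_maps(trim_edges(morlet_energy(x, r$grid$f_A, 5)),
                          r$per_fp$sections[[i]], 30,
                          r$per_fp$surrogate_seeds[[i]][1])),
    r$grid$f_P, r$grid$f_A)
  for (i in active)
    expect_lt(max(abs(colMeans(cmv$surrogate_values[, i, ]))), 1e-12)
  # global maximum at the simulated pair within one grid step
  am <- which(r$values == max(r$values, na.rm = TRUE), arr.ind = TRUE)
  expect_lte(abs(r$grid$f_P[am[1]] - 6), 1)
  expect_lte(abs(r$grid$f_A[am[2]] - 77), wavelet_fwhm_freq(77, 5) / 2)
  # significant pair present and phase-locked at the burst phase bin
  expect_true(any(r$mask))
})

test_that("phase distributions are normalized and peak at the burst phase", {
  x <- gen_coupled_bursts(burst_params(noise_level = 0.05), seed = 19)
  r <- emi_pac(x, f_P = c(5, 6, 7), f_A = seq(40, 120, 5),
               n_surrogates = 40, seed = 7)
  i6 <- which(r$grid$f_P == 6)
  expect_equal(r$status[i6], "analysed")
  P <- r$phase$P[i6, , ]
  expect_equal(rowSums(P), rep(1, length(r$grid$f_A)), tolerance = 1e-9)
  # modal bin of the 77 Hz row corresponds to the burst phase (the slow
  # peak, analytic phase ~ pi/2... after cycle alignment the peak sits at
  # the centre of the window where phase is near +pi/2)
  i77 <- which.min(abs(r$grid$f_A - 77))
  modal <- which.max(P[i77, ])
  centers <- -pi + (seq_len(18) - 0.5) * 2 * pi / 18
  sec <- r$per_fp$sections[[i6]]
  expected_phase <- sec$phase_A[which.max(sec$M_A[, i77])]
  d <- abs(((centers[modal] - expected_phase) + pi) %% (2 * pi) - pi)
  expect_lt(d, 2 * pi / 18 + 1e-9)
})

test_that("section spectra normalize to 1 and separate locked from random bursts", {
  f_A_rng <- c(40, 120)
  spec_peak_ratio <- function(x) {
    s6 <- extract_low_freq(x, 6, 1)
    cm <- find_cycle_maxima(s6, 6)
    E <- trim_edges(morlet_energy(x, seq(40, 120, 10), w = 5))
    sec <- average_sections(E, s6, x, cm)
    sp <- section_spectra(x, sec, f_A_rng)
    expect_equal(sum(sp$AS), 1, tolerance = 1e-9)
    expect_equal(sum(sp$SA), 1, tolerance = 1e-9)
    i77 <- which.min(abs(sp$freq - 77))
    sp$SA[i77] / sp$AS[i77]
  }
  # phase-locked bursts survive averaging: SA peak >= AS peak at 77 Hz
  r_locked <- spec_peak_ratio(gen_coupled_bursts(burst_params(), seed = 23))
  # random-phase bursts cancel in the average
  r_random <- spec_peak_ratio(gen_random_bursts(burst_params(), seed = 23))
  expect_gte(r_locked, 1)
  expect_lt(r_random, r_locked)
})

test_that("uncoupled controls rarely produce significant pairs", {
  hits <- 0
  for (s in 1:8) {
    x <- gen_filtered_noise_hf(noise_level = 0.1, seed = 400 + s)
    r <- emi_pac(x, f_P = seq(4, 8, 1), f_A = seq(60, 100, 5),
                 n_surrogates = 50, n_pink = 60, seed = 500 + s)
    hits <- hits + any(r$mask)
  }
  expect_lte(hits, 2)
})

test_that("amplitude rescaling leaves the significance mask unchanged", {
  x <- gen_coupled_bursts(burst_params(), seed = 29)
  r1 <- emi_pac(x, f_P = c(5, 6, 7), f_A = seq(40, 120, 10),
                n_surrogates = 40, n_pink = 60, seed = 6)
  xs <- pac_ts(4.2 * x$samples, x$fs)
  r2 <- emi_pac(xs, f_P = c(5, 6, 7), f_A = seq(40, 120, 10),
                n_surrogates = 40, n_pink = 60, seed = 6)
  expect_identical(r1$mask, r2$mask)
})
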