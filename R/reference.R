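# Reference PAC estimators: the direct PAC estimator (dPAC) and the
# Kullback-Leibler modulation index (MI), with the white-noise
# surrogate-phase scheme and extreme-value significance shared by both.

#' Comodulogram frequency grid
#'
#' @param f_P strictly increasing vector of frequencies for phase (Hz).
#' @param f_A strictly increasing vector of frequencies for amplitude (Hz);
#'   must lie entirely above `max(f_P)`.
#' @param delta_f_P bandwidth of the low-frequency filters (Hz).
#' @return list of class `pac_grid`.
#' @export
pac_grid <- function(f_P, f_A, delta_f_P = 1) {
  stopifnot(length(f_P) >= 1, length(f_A) >= 1, delta_f_P > 0)
  if (is.unsorted(f_P, strictly = TRUE) || is.unsorted(f_A, strictly = TRUE))
    stop("`f_P` and `f_A` must be strictly increasing")
  if (max(f_P) >= min(f_A)) stop("max(f_P) must be below min(f_A)")
  structure(list(f_P = f_P, f_A = f_A, delta_f_P = delta_f_P),
            class = "pac_grid")
}

#' Direct PAC estimator (dPAC) for one phase/amplitude pair
#'
#' `dPAC = (1 / sqrt(N)) * |sum(A * exp(i * phi))| / sqrt(sum(A^2))`, where
#' `N` is the number of samples. The value lies in `[0, 1]` and equals 1 for
#' constant amplitude at constant phase.
#'
#' @param pa a `pac_phase_amp` object (see [analytic_phase_amp()]) or a list
#'   with `phase` and `amplitude` vectors of equal length.
#' @return scalar in `[0, 1]`.
#' @export
dpac <- function(pa) {
  A <- pa$amplitude
  phi <- pa$phase
  stopifnot(length(A) == length(phi))
  if (all(A == 0)) stop("all-zero amplitude: dPAC normalization undefined")
  n <- length(A)
  Mod(sum(A * exp(1i * phi))) / (sqrt(n) * sqrt(sum(A^2)))
}

# mean amplitude per phase bin; empty bins yield 0
bin_mean_amplitude <- function(phase, amplitude, J) {
  bins <- pmin(pmax(floor((phase + pi) / (2 * pi) * J) + 1L, 1L), J)
  sums <- counts <- numeric(J)
  t1 <- tapply(amplitude, factor(bins, levels = 1:J), sum)
  sums <- ifelse(is.na(t1), 0, t1)
  t2 <- tabulate(bins, J)
  ifelse(t2 > 0, sums / pmax(t2, 1), 0)
}

mi_from_P <- function(P) {
  nz <- P > 0
  (log(length(P)) + sum(P[nz] * log(P[nz]))) / log(length(P))
}

#' Kullback-Leibler modulation index (MI) for one phase/amplitude pair
#'
#' The phase range `[-pi, pi]` is divided into `J` bins; the mean amplitude
#' per bin is normalised into a distribution `P(j)`, and
#' `MI = KL(P, uniform) / log(J)`, so that `MI = 0` for a uniform amplitude
#' distribution and `MI = 1` when all amplitude mass falls in one bin. Empty
#' bins contribute a mean amplitude of 0 and their `0 log 0` term is
#' dropped.
#'
#' @inheritParams dpac
#' @param J number of phase bins (default 18).
#' @return scalar in `[0, 1]`.
#' @export
mi <- function(pa, J = 18) {
  stopifnot(J >= 2, length(pa$amplitude) == length(pa$phase))
  if (all(pa$amplitude == 0)) stop("all-zero amplitude: MI undefined")
  m <- bin_mean_amplitude(pa$phase, pa$amplitude, J)
  mi_from_P(m / sum(m))
}

# ---- vectorised internals shared by comodulogram and surrogate loops ----

# FIR band definitions of the reference methods
ref_bands <- function(grid, fs) {
  half_hi <- max(grid$f_P)  # high-frequency half-bandwidth = max(f_P)
  list(
    phase = lapply(grid$f_P, function(f)
      c(f - grid$delta_f_P / 2, f + grid$delta_f_P / 2)),
    amp = lapply(grid$f_A, function(f) c(f - half_hi, f + half_hi))
  )
}

check_ref_grid <- function(grid, fs) {
  b <- ref_bands(grid, fs)
  for (k in seq_along(b$amp)) {
    if (b$amp[[k]][2] >= fs / 2)
      stop(sprintf("amplitude band for f_A = %g Hz exceeds Nyquist (%g Hz)",
                   grid$f_A[k], fs / 2))
  }
  for (k in seq_along(b$phase))
    if (b$phase[[k]][1] <= 0)
      stop(sprintf("phase band for f_P = %g Hz reaches 0 Hz", grid$f_P[k]))
  b
}

# filter bank outputs: amplitude envelopes (N x nA), phase series and unit
# phasors (N x nP) of the original signal. Phase rows whose FIR filter does
# not fit the signal (order > n/3) are dropped as NA columns; amplitude
# bands must always fit.
ref_phase_amp_bank <- function(x, grid) {
  bands <- check_ref_grid(grid, x$fs)
  n <- length(x$samples)
  amp <- vapply(bands$amp, function(bd)
    Mod(analytic_signal(fir_zerophase(
      x$samples, signal::fir1(ref_fir_order(x$fs, bd, n),
                              bd / (x$fs / 2), type = "pass")))),
    numeric(n))
  ok <- vapply(bands$phase, function(bd)
    n >= 3L * fir_order_3cyc(x$fs, bd[1]), logical(1))
  if (!any(ok))
    stop(sprintf("signal too short (%d samples) for any phase-band filter",
                 n))
  an <- matrix(NA_complex_, n, length(bands$phase))
  for (i in which(ok)) {
    bd <- bands$phase[[i]]
    a <- analytic_signal(fir_zerophase(
      x$samples, signal::fir1(ref_fir_order(x$fs, bd, n),
                              bd / (x$fs / 2), type = "pass")))
    an[, i] <- a / Mod(a)
  }
  list(amp = amp, phase = Arg(an), phasor = an, phase_ok = ok, bands = bands)
}

ref_fir_order <- function(fs, band, n) {
  ord <- fir_order_3cyc(fs, band[1])
  if (n < 3L * ord)
    stop(sprintf("signal too short (%d samples) for FIR order %d on band [%g, %g] Hz",
                 n, ord, band[1], band[2]))
  ord
}

ref_values <- function(phase_mat, amp_mat, method, J, edge_drop = 0L,
                       phasor_mat = NULL) {
  keep <- if (edge_drop > 0)
    (edge_drop + 1L):(nrow(amp_mat) - edge_drop) else seq_len(nrow(amp_mat))
  am <- amp_mat[keep, , drop = FALSE]
  if (method == "mi") {
    ph <- phase_mat[keep, , drop = FALSE]
    valid <- !is.na(ph[1, ])
    out <- matrix(NA_real_, ncol(ph), ncol(am))
    if (any(valid))
      out[valid, ] <- mi_cols_batch(ph[, valid, drop = FALSE], am, J)
    return(out)
  }
  if (is.null(phasor_mat)) phasor_mat <- exp(1i * phase_mat)
  pm <- phasor_mat[keep, , drop = FALSE]
  valid <- !is.na(pm[1, ])
  out <- matrix(NA_real_, ncol(pm), ncol(am))
  if (any(valid))
    out[valid, ] <- dpac_cols_batch(Re(pm[, valid, drop = FALSE]),
                                    Im(pm[, valid, drop = FALSE]), am)
  out
}

#' Reference-method comodulogram (MI or dPAC)
#'
#' Filters the signal around every `f_P` (bandwidth `delta_f_P`) and every
#' `f_A` (bandwidth twice `max(f_P)`) with zero-phase FIR filters, takes
#' instantaneous phase/amplitude from the analytic signal, and evaluates the
#' chosen estimator for every frequency pair. For dPAC the first and last
#' second are excluded after filtering; MI uses the full series.
#'
#' @param x a [pac_ts()] of duration above 2 s for dPAC.
#' @param grid a [pac_grid()].
#' @param method `"mi"` or `"dpac"`.
#' @param J number of phase bins for MI.
#' @return list of class `pac_comodulogram` with `values` (matrix
#'   `f_P x f_A`), `grid` and `method`.
#' @export
reference_comodulogram <- function(x, grid, method = c("mi", "dpac"), J = 18) {
  assert_ts(x)
  method <- match.arg(method)
  if (method == "dpac" && x$duration <= 2)
    stop("dPAC requires duration > 2 s (first and last second are discarded)")
  bank <- ref_phase_amp_bank(x, grid)
  edge <- if (method == "dpac") round(x$fs) else 0L
  vals <- ref_values(bank$phase, bank$amp, method, J, edge, bank$phasor)
  structure(list(values = vals, grid = grid, method = method),
            class = "pac_comodulogram")
}

#' Surrogate comodulograms for the reference methods
#'
#' Each surrogate replaces the instantaneous phase by the phase of white
#' Gaussian noise filtered with the same low-frequency filters; the
#' amplitude series are left untouched.
#'
#' @inheritParams reference_comodulogram
#' @param n_surrogates number of surrogate comodulograms.
#' @param seed integer seed.
#' @return list of `pac_comodulogram` objects of length `n_surrogates`.
#' @export
reference_surrogates <- function(x, grid, method = c("mi", "dpac"), J = 18,
                                 n_surrogates = 200, seed = 1) {
  method <- match.arg(method)
  sig <- reference_significance(x, grid, methods = method, J = J,
                                n_surrogates = n_surrogates, seed = seed,
                                keep_surrogates = TRUE)
  lapply(seq_len(n_surrogates), function(s)
    structure(list(values = sig[[method]]$surrogates[[s]], grid = grid,
                   method = method),
              class = "pac_comodulogram"))
}

#' Reference-method significance by extreme-value statistics
#'
#' Computes the original comodulogram(s) and `n_surrogates` surrogate
#' comodulograms (shared surrogate phases when both methods are requested),
#' then thresholds at the `p_C` percentile of the per-surrogate maxima.
#'
#' @inheritParams reference_surrogates
#' @param methods character subset of `c("mi", "dpac")`.
#' @param p_C percentile of the extreme-value distribution (default 95).
#' @param keep_surrogates keep the individual surrogate matrices (memory).
#' @return named list per method with `values`, `threshold`, `mask`,
#'   `P_vals` and `surr_max`; see [extreme_value_threshold()].
#' @export
reference_significance <- function(x, grid, methods = c("mi", "dpac"), J = 18,
                                   n_surrogates = 200, p_C = 95, seed = 1,
                                   keep_surrogates = FALSE) {
  assert_ts(x)
  methods <- match.arg(methods, c("mi", "dpac"), several.ok = TRUE)
  bank <- ref_phase_amp_bank(x, grid)
  n <- length(x$samples)
  fs <- x$fs
  edge <- round(fs)
  if ("dpac" %in% methods && x$duration <= 2)
    stop("dPAC requires duration > 2 s")
  orig <- list()
  for (m in methods)
    orig[[m]] <- ref_values(bank$phase, bank$amp, m, J,
                            if (m == "dpac") edge else 0L, bank$phasor)

  seeds <- child_seeds(seed, length(grid$f_P))
  # surrogate phases: one N x n_surrogates matrix per f_P, filtered in a batch
  surr_phase <- surr_phasor <- vector("list", length(grid$f_P))
  for (i in seq_along(grid$f_P)) {
    if (!bank$phase_ok[i]) {
      surr_phasor[[i]] <- matrix(NA_complex_, n, n_surrogates)
      surr_phase[[i]] <- matrix(NA_real_, n, n_surrogates)
      next
    }
    bd <- bank$bands$phase[[i]]
    b <- signal::fir1(ref_fir_order(fs, bd, n), bd / (fs / 2), type = "pass")
    noise <- with_seed(seeds[i],
                       matrix(stats::rnorm(n * n_surrogates), n, n_surrogates))
    an <- analytic_mat(fir_zerophase(noise, b))
    an <- an / Mod(an)
    surr_phasor[[i]] <- an
    surr_phase[[i]] <- Arg(an)
  }

  surr_max <- stats::setNames(
    rep(list(numeric(n_surrogates)), length(methods)), methods)
  surr_store <- stats::setNames(
    rep(list(vector("list", n_surrogates)), length(methods)), methods)
  for (s in seq_len(n_surrogates)) {
    ph <- if ("mi" %in% methods)
      vapply(surr_phase, function(m) m[, s], numeric(n)) else NULL
    phs <- vapply(surr_phasor, function(m) m[, s], complex(n))
    for (m in methods) {
      v <- ref_values(ph, bank$amp, m, J, if (m == "dpac") edge else 0L, phs)
      surr_max[[m]][s] <- max(v, na.rm = TRUE)
      if (keep_surrogates) surr_store[[m]][[s]] <- v
    }
  }
  out <- list()
  for (m in methods) {
    sig <- extreme_value_threshold(orig[[m]], surr_max[[m]], p_C = p_C)
    out[[m]] <- c(list(values = orig[[m]], grid = grid, method = m), sig)
    if (keep_surrogates) out[[m]]$surrogates <- surr_store[[m]]
  }
  out
}
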