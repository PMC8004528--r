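# The eMI pipeline: screening of phase frequencies against a pink-noise
# background, cycle-locked averaging of the wavelet energy map (paths A and
# B), jitter/stretch surrogate maps, comodulogram construction with
# surrogate-mean centering, per-pair phase-bin distributions and section
# spectra.

# ---- low-frequency screening ------------------------------------------------

# background level of a PSD: piecewise-cubic (pchip) interpolation through
# its strict local minima in log10 space, endpoints appended as anchors;
# falls back to the linear trend through the endpoints when fewer than two
# interior minima exist
spectrum_background <- function(freq, psd) {
  use <- freq > 0
  f <- freq[use]
  lp <- log10(pmax(psd[use], .Machine$double.xmin))
  n <- length(lp)
  imin <- which(diff(sign(diff(lp))) > 0) + 1L
  fallback <- length(imin) < 2L
  if (fallback) {
    bg <- lp[1] + (lp[n] - lp[1]) * (f - f[1]) / (f[n] - f[1])
  } else {
    anchors <- unique(c(1L, imin, n))
    bg <- pracma::pchip(f[anchors], lp[anchors], f)
  }
  out <- rep(NA_real_, length(freq))
  out[use] <- 10^bg
  list(background = out, fallback = fallback)
}

#' Screen phase frequencies against a pink-noise background
#'
#' Estimates the Welch PSD of the signal and its background level
#' (piecewise-cubic interpolation through the spectral minima), and compares
#' the spectrum-to-background ratio at each candidate phase frequency with
#' the `pct` percentile of the same ratio computed on `n_pink` pink-noise
#' realisations of equal length. Frequencies whose ratio exceeds the
#' pink-noise threshold carry a genuine oscillation and pass to the eMI
#' analysis.
#'
#' @param x a [pac_ts()] covering several cycles of `min(f_P)`.
#' @param f_P candidate phase frequencies (Hz).
#' @param n_pink number of pink-noise realisations (default 200).
#' @param pct percentile of the pink-noise ratio distribution (default 95).
#' @param seed integer seed.
#' @return list of class `lowfreq_screen` with `f_P`, `ratio`, `threshold`,
#'   `significant` and `fallback` (background interpolation fell back to a
#'   linear trend).
#' @export
screen_phase_frequencies <- function(x, f_P, n_pink = 200, pct = 95,
                                     seed = 1) {
  assert_ts(x)
  n <- length(x$samples)
  seg_s <- max(2, 4 / min(f_P))
  seg_len <- min(n, round(x$fs * seg_s))
  ratio_at <- function(sig) {
    ps <- welch_psd(sig, x$fs, seg_len)
    bg <- spectrum_background(ps$freq, ps$psd)
    idx <- vapply(f_P, function(f) which.min(abs(ps$freq - f)), integer(1))
    list(r = ps$psd[idx] / bg$background[idx], fallback = bg$fallback)
  }
  orig <- ratio_at(x$samples)
  seeds <- child_seeds(seed, n_pink)
  pink_ratios <- vapply(seeds, function(s)
    ratio_at(gen_pink_noise(n, x$fs, s)$samples)$r, numeric(length(f_P)))
  pink_ratios <- matrix(pink_ratios, nrow = length(f_P))
  thr <- apply(pink_ratios, 1, pctile, p = pct)
  structure(list(f_P = f_P, ratio = orig$r, threshold = thr,
                 significant = orig$r > thr, fallback = orig$fallback),
            class = "lowfreq_screen")
}

# ---- cycle maxima -----------------------------------------------------------

odd_len <- function(k) { k <- max(1L, round(k)); if (k %% 2 == 0) k + 1L else k }

greedy_nonoverlap <- function(idx, half) {
  kept <- integer()
  last <- -Inf
  for (i in idx) {
    if (i - half > last) { kept <- c(kept, i); last <- i + half }
  }
  kept
}

#' Locate low-frequency cycle maxima and section centres
#'
#' Detects local maxima of the filtered low-frequency trace, discards those
#' with topographic prominence below 5% of the median prominence, excludes
#' maxima within `1.5 / f_P` of either signal end, and greedily selects,
#' from the first retained maximum onward, the non-overlapping section
#' centres for the one-cycle (path A) and three-cycle (path B) windows.
#' When fewer than 3 path-A sections remain, the frequency is abandoned.
#'
#' @param s_fP a [pac_ts()]: the band-passed low-frequency trace.
#' @param f_P its centre frequency (Hz).
#' @return list of class `cycle_maxima` with retained maxima (`index`,
#'   `times`, `prominence`), selections `sel_A`/`sel_B` (sample indices of
#'   the kept centres), odd window lengths `len_A`/`len_B`, counts
#'   `n_A`/`n_B`, and `abandoned`/`reason`.
#' @export
find_cycle_maxima <- function(s_fP, f_P) {
  assert_ts(s_fP)
  fs <- s_fP$fs
  T_sig <- s_fP$duration
  res <- list(f_P = f_P, fs = fs,
              len_A = odd_len(fs / f_P), len_B = odd_len(3 * fs / f_P),
              abandoned = FALSE, reason = NULL)
  pk <- find_peaks_prominence(s_fP$samples)
  if (nrow(pk)) {
    pk <- pk[pk$prominence >= 0.05 * stats::median(pk$prominence), , drop = FALSE]
    tms <- (pk$index - 1) / fs
    edge <- 1.5 / f_P
    keep <- tms >= edge & tms <= T_sig - edge
    pk <- pk[keep, , drop = FALSE]
  }
  res$index <- pk$index
  res$times <- (pk$index - 1) / fs
  res$prominence <- pk$prominence
  res$sel_A <- greedy_nonoverlap(pk$index, (res$len_A - 1) / 2)
  res$sel_B <- greedy_nonoverlap(pk$index, (res$len_B - 1) / 2)
  res$n_A <- length(res$sel_A)
  res$n_B <- length(res$sel_B)
  if (res$n_A < 3) {
    res$abandoned <- TRUE
    res$reason <- "insufficient cycles"
  }
  structure(res, class = "cycle_maxima")
}

# ---- cycle-locked averaging -------------------------------------------------

# centres whose window [c - half, c + half] fits inside the trimmed map
fit_in_map <- function(centers, half, E) {
  lo <- E$i0 + 1L
  hi <- E$i0 + nrow(E$energy)
  centers[centers - half >= lo & centers + half <= hi]
}

avg_map_sections <- function(E, centers, half) {
  L <- 2L * half + 1L
  acc <- matrix(0, L, ncol(E$energy))
  for (c in centers) {
    rows <- (c - half):(c + half) - E$i0
    acc <- acc + E$energy[rows, , drop = FALSE]
  }
  acc / length(centers)
}

avg_signal_sections <- function(v, centers, half) {
  rowMeans(vapply(centers, function(c) v[(c - half):(c + half)],
                  numeric(2L * half + 1L)))
}

#' Cycle-locked averages of the energy map and signal
#'
#' Averages one-cycle (path A) and three-cycle (path B) sections of the
#' trimmed wavelet energy map, the filtered low-frequency trace and the raw
#' signal, centred on the selected cycle maxima. Centres whose window
#' exceeds the trimmed map extent are dropped (and counted). The phase axis
#' of path A is the instantaneous phase of the averaged low-frequency cycle.
#'
#' @param E a trimmed `pac_tfmap` (see [trim_edges()]).
#' @param s_fP the band-passed low-frequency [pac_ts()].
#' @param x the raw [pac_ts()].
#' @param cm a `cycle_maxima` object.
#' @return list of class `averaged_sections` with `M_A`, `SP_A`, `phase_A`
#'   (path A), `M_B`, `SP_B`, `S_B` (path B), the retained centres and
#'   counts, or `NULL` when fewer than 3 path-A sections fit the map.
#' @export
average_sections <- function(E, s_fP, x, cm) {
  stopifnot(inherits(E, "pac_tfmap"), inherits(cm, "cycle_maxima"))
  if (cm$abandoned) stop("cycle maxima are abandoned: ", cm$reason)
  half_A <- (cm$len_A - 1L) / 2L
  half_B <- (cm$len_B - 1L) / 2L
  cA <- fit_in_map(cm$sel_A, half_A, E)
  cB <- fit_in_map(cm$sel_B, half_B, E)
  if (length(cA) < 3) return(NULL)
  SP_A <- avg_signal_sections(s_fP$samples, cA, half_A)
  res <- list(
    M_A = avg_map_sections(E, cA, half_A),
    SP_A = SP_A,
    phase_A = Arg(analytic_signal(SP_A)),
    centers_A = cA, n_A = length(cA),
    dropped_A = length(cm$sel_A) - length(cA),
    len_A = cm$len_A, len_B = cm$len_B,
    f_P = cm$f_P, fs = cm$fs, freqs = E$freqs
  )
  if (length(cB) >= 1) {
    res$M_B <- avg_map_sections(E, cB, half_B)
    res$SP_B <- avg_signal_sections(s_fP$samples, cB, half_B)
    res$S_B <- avg_signal_sections(x$samples, cB, half_B)
    res$centers_B <- cB
    res$n_B <- length(cB)
    res$dropped_B <- length(cm$sel_B) - length(cB)
  } else {
    res$n_B <- 0L
    res$dropped_B <- length(cm$sel_B)
  }
  structure(res, class = "averaged_sections")
}

# ---- surrogate maps ---------------------------------------------------------

#' Jitter/stretch surrogate averaged maps
#'
#' For each surrogate repetition, every path-A section centre is displaced
#' by a uniform random offset in `(-1/(2 f_P), +1/(2 f_P))` seconds and its
#' window is squeezed or stretched by an independent factor drawn from
#' `U(0.9, 1.1)` (a window of `dt_A / factor` seconds is read from the map
#' and resampled by linear interpolation back to the path-A sample count).
#' Sections are averaged into one surrogate map per repetition. Displaced
#' windows falling outside the map are redrawn up to 10 times, then the
#' centre is skipped.
#'
#' @param E a trimmed `pac_tfmap`.
#' @param sections an `averaged_sections` object (supplies the retained
#'   centres).
#' @param n_surrogates number of repetitions.
#' @param seed integer seed.
#' @return list of class `surrogate_ensemble` with `maps` (list of
#'   `len_A x n_freq` matrices), `seeds` and `n_skipped`.
#' @export
surrogate_maps <- function(E, sections, n_surrogates = 200, seed = 1) {
  stopifnot(inherits(E, "pac_tfmap"), inherits(sections, "averaged_sections"))
  f_P <- sections$f_P
  fs <- sections$fs
  half <- (sections$len_A - 1L) / 2L
  L <- sections$len_A
  rel <- (-half:half) / fs
  t_cent <- (sections$centers_A - 1) / fs
  t_lo <- E$times[1]
  t_hi <- E$times[length(E$times)]
  nt <- nrow(E$energy)
  nf <- ncol(E$energy)
  seeds <- child_seeds(seed, n_surrogates)
  maps <- vector("list", n_surrogates)
  n_skipped <- integer(n_surrogates)
  for (s in seq_len(n_surrogates)) {
    with_seed(seeds[s], {
      src <- matrix(NA_real_, L, length(t_cent))
      ok <- logical(length(t_cent))
      for (k in seq_along(t_cent)) {
        r <- stats::runif(1, 0.9, 1.1)
        for (try in 1:10) {
          jit <- stats::runif(1, -1 / (2 * f_P), 1 / (2 * f_P))
          cand <- t_cent[k] + jit + rel / r
          if (cand[1] >= t_lo && cand[L] <= t_hi) {
            src[, k] <- cand; ok[k] <- TRUE; break
          }
        }
      }
      n_skipped[s] <- sum(!ok)
      src <- src[, ok, drop = FALSE]
      fi <- (src - t_lo) * fs + 1
      lo <- pmin(pmax(floor(fi), 1), nt - 1)
      wf <- pmin(pmax(fi - lo, 0), 1)
      M <- matrix(0, L, nf)
      for (j in seq_len(nf)) {
        col <- E$energy[, j]
        vals <- col[lo] * (1 - wf) + col[lo + 1L] * wf
        M[, j] <- rowMeans(matrix(vals, L))
      }
      maps[[s]] <- M
    })
  }
  structure(list(maps = maps, seeds = seeds, n_skipped = n_skipped),
            class = "surrogate_ensemble")
}

# ---- phase-bin machinery ----------------------------------------------------

# normalized amplitude-over-phase-bin distribution, one column per
# amplitude series: returns a J x ncol(amp_mat) matrix with unit column sums
p_cols <- function(phase, amp_mat, J) {
  bins <- pmin(pmax(floor((phase + pi) / (2 * pi) * J) + 1L, 1L), J)
  ind <- matrix(0, length(bins), J)
  ind[cbind(seq_along(bins), bins)] <- 1
  means <- crossprod(ind, amp_mat) / pmax(colSums(ind), 1)
  sweep(means, 2, colSums(means), "/")
}

# MI of every column of a bin-distribution matrix (Kullback-Leibler from
# uniform, normalized by log J)
mi_from_P_cols <- function(P) {
  PL <- P * log(P)
  PL[P == 0] <- 0
  (log(nrow(P)) + colSums(PL)) / log(nrow(P))
}

# ---- comodulogram -----------------------------------------------------------

#' eMI comodulogram with surrogate-mean centering
#'
#' For every analysed phase frequency, MI is evaluated with the path-A phase
#' axis against each frequency row of the averaged map (original) and of
#' each surrogate map; original and surrogate values are then centred by the
#' per-pair surrogate mean, making values comparable across pairs.
#'
#' @param sections_list list (one element per `f_P`, `NULL` where the
#'   frequency was not analysed) of `averaged_sections`.
#' @param surrogates_list matching list of `surrogate_ensemble`s.
#' @param f_P,f_A the grid axes (Hz).
#' @param J number of phase bins.
#' @return list with `values` (centred comodulogram, `f_P x f_A`, `NA` rows
#'   for unanalysed frequencies), `surrogate_values` (array
#'   `n_surrogates x f_P x f_A`), and `raw` (uncentred original MI).
#' @export
emi_comodulogram <- function(sections_list, surrogates_list, f_P, f_A,
                             J = 18) {
  nP <- length(f_P); nA <- length(f_A)
  n_s <- 0
  for (su in surrogates_list) if (!is.null(su)) n_s <- max(n_s, length(su$maps))
  vals <- raw <- matrix(NA_real_, nP, nA)
  surr <- array(NA_real_, c(max(n_s, 1), nP, nA))
  for (i in seq_len(nP)) {
    sec <- sections_list[[i]]
    su <- surrogates_list[[i]]
    if (is.null(sec) || is.null(su)) next
    orig <- mi_from_P_cols(p_cols(sec$phase_A, sec$M_A, J))
    smi <- t(vapply(su$maps, function(m)
      mi_from_P_cols(p_cols(sec$phase_A, m, J)), numeric(nA)))
    mu <- colMeans(smi)
    raw[i, ] <- orig
    vals[i, ] <- orig - mu
    surr[, i, ] <- sweep(smi, 2, mu)
  }
  list(values = vals, surrogate_values = surr, raw = raw)
}

#' Per-pair phase-bin distributions and surrogate bin thresholds
#'
#' Saves the normalised mean-power-per-phase-bin distribution `P(j)` for
#' every frequency pair, and the per-pair threshold at the `p_PC` percentile
#' of the distribution over surrogates of `max_j P_s(j)`.
#'
#' @inheritParams emi_comodulogram
#' @param p_PC percentile for the bin threshold (default 95).
#' @return list of class `phase_distribution` with `P` (array
#'   `f_P x f_A x J`), `th` (matrix `f_P x f_A`) and `J`.
#' @export
phase_distributions <- function(sections_list, surrogates_list, f_P, f_A,
                                J = 18, p_PC = 95) {
  nP <- length(f_P); nA <- length(f_A)
  P <- array(NA_real_, c(nP, nA, J))
  th <- matrix(NA_real_, nP, nA)
  for (i in seq_len(nP)) {
    sec <- sections_list[[i]]
    su <- surrogates_list[[i]]
    if (is.null(sec) || is.null(su)) next
    P[i, , ] <- t(p_cols(sec$phase_A, sec$M_A, J))
    maxP <- vapply(su$maps, function(m)
      apply(p_cols(sec$phase_A, m, J), 2, max), numeric(nA))
    th[i, ] <- apply(matrix(maxP, nrow = nA), 1, pctile, p = p_PC)
  }
  structure(list(P = P, th = th, J = J), class = "phase_distribution")
}

# ---- section spectra --------------------------------------------------------

#' Average spectrum and spectrum of the averaged signal
#'
#' For each path-B section of the raw signal a Blackman-Harris periodogram
#' is computed; their mean, restricted to the amplitude-frequency range and
#' normalised to unit total power, is the average spectrum `AS`. The same
#' estimator applied to the averaged signal `S_B` gives `SA`. Synchronised
#' high-frequency activity survives averaging and shows as a peak in `SA`;
#' activity with random phase averages out and only shows in `AS`.
#'
#' @param x the raw [pac_ts()].
#' @param sections an `averaged_sections` object with path-B content.
#' @param f_A_range numeric `c(lo, hi)` in Hz.
#' @return list of class `section_spectra` with `freq`, `AS`, `SA` (both
#'   summing to 1 over `freq`), or `NULL` when no path-B sections exist.
#' @export
section_spectra <- function(x, sections, f_A_range) {
  stopifnot(inherits(sections, "averaged_sections"))
  if (is.null(sections$n_B) || sections$n_B < 1) return(NULL)
  half <- (sections$len_B - 1L) / 2L
  specs <- vapply(sections$centers_B, function(c)
    bh_periodogram(x$samples[(c - half):(c + half)], x$fs)$psd,
    numeric(sections$len_B %/% 2 + 1L))
  freq <- bh_periodogram(x$samples[1:sections$len_B], x$fs)$freq
  sel <- freq >= f_A_range[1] & freq <= f_A_range[2]
  if (!any(sel)) return(NULL)
  AS <- rowMeans(specs)[sel]
  SA <- bh_periodogram(sections$S_B, x$fs)$psd[sel]
  structure(list(freq = freq[sel], AS = AS / sum(AS), SA = SA / sum(SA)),
            class = "section_spectra")
}

# ---- full pipeline ----------------------------------------------------------

#' Extended Modulation Index analysis
#'
#' Runs the complete eMI pipeline on a single-channel time series: screening
#' of phase frequencies against a pink-noise background, Butterworth
#' extraction of each significant low-frequency oscillation, cycle-maxima
#' detection, cycle-locked averaging of the Morlet energy map, jitter/stretch
#' surrogate maps, comodulogram construction with surrogate-mean centering,
#' extreme-value significance, phase-bin thresholding, and
#' Reliable/Ambiguous labeling of each significant region.
#'
#' @param x a [pac_ts()].
#' @param f_P phase-frequency grid (Hz).
#' @param f_A amplitude-frequency grid (Hz).
#' @param delta_f_P low-frequency filter bandwidth (Hz).
#' @param w Morlet wavenumber.
#' @param J number of phase bins.
#' @param n_surrogates surrogate repetitions (default 200).
#' @param p_C percentile for the comodulogram extreme-value threshold.
#' @param p_PC percentile for the per-pair phase-bin threshold.
#' @param n_pink pink-noise repetitions for the screening step.
#' @param seed master seed; all internal streams derive from it.
#' @param screen logical; set `FALSE` to analyse every `f_P` regardless of
#'   the spectral screen (used in calibration studies).
#' @return object of class `emi_pac`: centred comodulogram (`values`),
#'   significance (`threshold`, `mask_extreme`, `mask`, `P_vals`),
#'   phase-bin distributions (`phase`), labeled `regions` with a
#'   `label_matrix`, the screening result, and per-frequency auxiliaries
#'   (`per_fp`: sections, spectra, surrogate seeds, abandonment reasons).
#' @export
emi_pac <- function(x, f_P = seq(2, 10, by = 1), f_A = seq(40, 120, by = 5),
                    delta_f_P = 1, w = 5, J = 18, n_surrogates = 200,
                    p_C = 95, p_PC = 95, n_pink = 200, seed = 1,
                    screen = TRUE) {
  assert_ts(x)
  grid <- pac_grid(f_P, f_A, delta_f_P)
  seeds <- child_seeds(seed, 1L + length(f_P))
  scr <- if (screen) {
    screen_phase_frequencies(x, f_P, n_pink = n_pink, seed = seeds[1])
  } else {
    structure(list(f_P = f_P, ratio = rep(NA_real_, length(f_P)),
                   threshold = rep(NA_real_, length(f_P)),
                   significant = rep(TRUE, length(f_P)), fallback = FALSE),
              class = "lowfreq_screen")
  }
  E <- trim_edges(morlet_energy(x, f_A, w))
  nP <- length(f_P)
  sections_list <- vector("list", nP)
  surr_list <- vector("list", nP)
  spectra_list <- vector("list", nP)
  status <- rep("not significant", nP)
  for (i in seq_len(nP)) {
    if (!scr$significant[i]) next
    s_fP <- extract_low_freq(x, f_P[i], delta_f_P)
    cmx <- find_cycle_maxima(s_fP, f_P[i])
    if (cmx$abandoned) { status[i] <- cmx$reason; next }
    sec <- average_sections(E, s_fP, x, cmx)
    if (is.null(sec)) { status[i] <- "insufficient cycles"; next }
    sections_list[[i]] <- sec
    surr_list[[i]] <- surrogate_maps(E, sec, n_surrogates, seeds[1L + i])
    spectra_list[[i]] <- section_spectra(x, sec, range(f_A))
    status[i] <- "analysed"
  }
  cm <- emi_comodulogram(sections_list, surr_list, f_P, f_A, J)
  active <- !vapply(sections_list, is.null, logical(1))
  if (any(active)) {
    surr_max <- apply(cm$surrogate_values, 1, max, na.rm = TRUE)
    sig <- extreme_value_threshold(cm$values, surr_max, p_C = p_C)
    pd <- phase_distributions(sections_list, surr_list, f_P, f_A, J, p_PC)
    mask <- bin_threshold_filter(sig$mask, pd)
  } else {
    sig <- list(threshold = NA_real_,
                mask = matrix(FALSE, nP, length(f_A)),
                P_vals = matrix(NA_real_, nP, length(f_A)),
                surr_max = numeric())
    pd <- structure(list(P = array(NA_real_, c(nP, length(f_A), J)),
                         th = matrix(NA_real_, nP, length(f_A)), J = J),
                    class = "phase_distribution")
    mask <- sig$mask
  }
  lab <- label_regions(mask, cm$values, spectra_list, grid, w, pd)
  structure(list(
    values = cm$values, raw = cm$raw, grid = grid, w = w, J = J,
    threshold = sig$threshold, mask_extreme = sig$mask, mask = mask,
    P_vals = sig$P_vals, surr_max = sig$surr_max, p_C = p_C, p_PC = p_PC,
    phase = pd, screen = scr, status = status,
    regions = lab$regions, label_matrix = lab$label_matrix,
    per_fp = list(sections = sections_list, spectra = spectra_list,
                  surrogate_seeds = lapply(surr_list, function(s) s$seeds)),
    n_surrogates = n_surrogates, seed = seed
  ), class = "emi_pac")
}

#' @export
print.emi_pac <- function(x, ...) {
  nsig <- sum(x$mask, na.rm = TRUE)
  cat(sprintf("<emi_pac> grid %d f_P x %d f_A, w = %g, %d surrogates\n",
              length(x$grid$f_P), length(x$grid$f_A), x$w, x$n_surrogates))
  cat(sprintf("  analysed f_P: %s\n",
              paste(x$grid$f_P[x$status == "analysed"], collapse = ", ")))
  cat(sprintf("  significant pairs: %d in %d region(s)\n",
              nsig, length(x$regions)))
  for (r in x$regions)
    cat(sprintf("   region %d: f_P %g-%g Hz, f_A %g-%g Hz, %s\n",
                r$id, min(x$grid$f_P[r$cells[, 1]]),
                max(x$grid$f_P[r$cells[, 1]]),
                min(x$grid$f_A[r$cells[, 2]]),
                max(x$grid$f_A[r$cells[, 2]]), r$label))
  invisible(x)
}
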