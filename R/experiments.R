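# Scripted, seeded validation studies: false-positive calibration on the
# no-coupling models, single-parameter sweeps with detection percentages at
# the simulated pair, and the collated epoch time-evolution view.

sweep_models <- c("coupled_bursts", "random_bursts", "filtered_noise",
                  "am", "multimodal")

# build one realisation of a named model with one parameter overridden
build_model_signal <- function(model, parameter = NULL, value = NULL, seed) {
  set_par <- function(defaults) {
    if (!is.null(parameter)) defaults[[parameter]] <- value
    defaults
  }
  switch(model,
    coupled_bursts = {
      p <- list(amplitudes_ratio = 0.1, noise_level = 0.1, duration = 10,
                filling = 1)
      if (!is.null(parameter)) {
        if (parameter == "length") parameter <- "duration"
        p[[parameter]] <- value
      }
      gen_coupled_bursts(burst_params(
        amplitudes_ratio = p$amplitudes_ratio, noise_level = p$noise_level,
        duration = p$duration, filling = p$filling), seed)
    },
    random_bursts = {
      p <- set_par(list(noise_level = 0.1))
      gen_random_bursts(burst_params(noise_level = p$noise_level), seed)
    },
    filtered_noise = {
      p <- set_par(list(noise_level = 0.1))
      gen_filtered_noise_hf(noise_level = p$noise_level, seed = seed)
    },
    am = {
      p <- list(chi = 0.1, A_fA_bar = 0.1, A_N_bar = 0.1, duration = 10)
      if (!is.null(parameter)) {
        if (parameter == "depth_of_modulation") { parameter <- "chi"; value <- 1 - value }
        if (parameter == "amplitudes_ratio") parameter <- "A_fA_bar"
        if (parameter == "noise_level") parameter <- "A_N_bar"
        if (parameter == "length") parameter <- "duration"
        p[[parameter]] <- value
      }
      gen_amplitude_modulated(am_params(
        chi = p$chi, A_fA_bar = p$A_fA_bar, A_N_bar = p$A_N_bar,
        duration = p$duration), seed)
    },
    multimodal = {
      p <- set_par(list(n_modes = 1))
      gen_multimodal(multimodal_params(n_modes = p$n_modes), seed)
    },
    stop("unknown model: ", model)
  )
}

# run one method on one signal. The PAC value is read at the grid pair
# nearest (f_P0, f_A0); "detected" means a significant pair inside the
# simulated coupling's neighbourhood (f_P within 1 Hz, f_A within half the
# wavelet FWHM), i.e. detection of that coupling rather than of the exact
# grid cell. Errors (e.g. signals too short to filter) count as
# non-detections.
eval_methods_at_pair <- function(x, grid, methods, n_surrogates, seed,
                                 w = 5, f_P0 = 6, f_A0 = 77, ...) {
  iP <- which.min(abs(grid$f_P - f_P0))
  iA <- which.min(abs(grid$f_A - f_A0))
  near <- outer(abs(grid$f_P - f_P0) <= 1,
                abs(grid$f_A - f_A0) <= wavelet_fwhm_freq(f_A0, w) / 2)
  out <- list()
  sd2 <- child_seeds(seed, 2)
  ref <- intersect(methods, c("mi", "dpac"))
  if (length(ref)) {
    sig <- tryCatch(
      reference_significance(x, grid, methods = ref,
                             n_surrogates = n_surrogates, seed = sd2[1]),
      error = function(e) NULL)
    for (m in ref) {
      out[[m]] <- if (is.null(sig)) {
        list(value = NA_real_, detected = FALSE, any_detected = FALSE,
             label = NA_character_)
      } else {
        list(value = sig[[m]]$values[iP, iA],
             detected = any(sig[[m]]$mask & near),
             any_detected = any(sig[[m]]$mask),
             label = NA_character_)
      }
    }
  }
  if ("emi" %in% methods) {
    em <- tryCatch(
      emi_pac(x, f_P = grid$f_P, f_A = grid$f_A,
              delta_f_P = grid$delta_f_P, w = w,
              n_surrogates = n_surrogates, seed = sd2[2], ...),
      error = function(e) NULL)
    out$emi <- if (is.null(em)) {
      list(value = NA_real_, detected = FALSE, any_detected = FALSE,
           label = NA_character_)
    } else {
      hit <- em$mask & near
      list(value = em$values[iP, iA],
           detected = any(hit),
           any_detected = any(em$mask),
           label = if (any(hit)) {
             lbl <- em$label_matrix[hit]
             if (any(lbl == "Reliable", na.rm = TRUE)) "Reliable"
             else "Ambiguous"
           } else NA_character_)
    }
  }
  out[methods]
}

#' False-positive calibration experiment
#'
#' Generates seeded realisations of a no-coupling model at each noise level,
#' runs the requested methods with their surrogate significance test, and
#' reports the fraction of realisations whose comodulogram contains at
#' least one significant pair (the false positive ratio, expected near
#' `1 - p_C/100`).
#'
#' @param model `"random_bursts"` or `"filtered_noise"`.
#' @param noise_levels numeric vector of noise levels.
#' @param n_reps realisations per noise level.
#' @param n_surrogates surrogates per realisation.
#' @param grid a [pac_grid()].
#' @param methods subset of `c("emi", "mi", "dpac")`.
#' @param seed master seed.
#' @param ... further arguments to [emi_pac()].
#' @return data frame with columns `model`, `method`, `noise_level`, `fpr`,
#'   `n_reps`, plus `ambiguous_share` for eMI (fraction of detections
#'   labeled Ambiguous).
#' @export
run_fpr_experiment <- function(model = c("random_bursts", "filtered_noise"),
                               noise_levels = c(0, 0.1, 0.2),
                               n_reps = 50, n_surrogates = 50,
                               grid = pac_grid(seq(2, 10, 1), seq(40, 120, 5)),
                               methods = c("emi", "mi", "dpac"), seed = 1,
                               ...) {
  model <- match.arg(model)
  rows <- list()
  seeds <- matrix(child_seeds(seed, 2 * length(noise_levels) * n_reps),
                  ncol = 2)
  k <- 0L
  for (nl in noise_levels) {
    det <- stats::setNames(rep(list(logical(n_reps)), length(methods)),
                           methods)
    amb <- logical(0)
    for (r in seq_len(n_reps)) {
      k <- k + 1L
      x <- build_model_signal(model, "noise_level", nl, seeds[k, 1])
      ev <- eval_methods_at_pair(x, grid, methods, n_surrogates,
                                 seeds[k, 2], ...)
      for (m in methods) det[[m]][r] <- isTRUE(ev[[m]]$any_detected)
    }
    for (m in methods)
      rows[[length(rows) + 1L]] <- data.frame(
        model = model, method = m, noise_level = nl,
        fpr = mean(det[[m]]), n_reps = n_reps)
  }
  do.call(rbind, rows)
}

#' Single-parameter sweep of a coupling model
#'
#' Varies one parameter of a coupling model over a value grid with all
#' others at their defaults; for each value, `n_reps` seeded realisations
#' are analysed by each method, and the PAC value plus detection state at
#' the grid pair nearest (6, 77) Hz is recorded.
#'
#' @param model `"coupled_bursts"`, `"am"` or `"multimodal"`.
#' @param parameter one of `"amplitudes_ratio"`, `"noise_level"`,
#'   `"length"`, `"filling"`, `"depth_of_modulation"`, `"n_modes"`.
#' @param values numeric vector of parameter values.
#' @param n_reps seeded repetitions per value (default 10).
#' @inheritParams run_fpr_experiment
#' @return data frame of class `pac_sweep` with one row per (value, rep,
#'   method): `value`, `rep`, `method`, `pac`, `detected`, `label`.
#' @export
run_sweep <- function(model, parameter, values, n_reps = 10,
                      n_surrogates = 100,
                      grid = pac_grid(seq(2, 10, 1), seq(40, 120, 5)),
                      methods = c("emi", "mi", "dpac"), seed = 1, ...) {
  stopifnot(model %in% sweep_models,
            parameter %in% c("amplitudes_ratio", "noise_level", "length",
                             "filling", "depth_of_modulation", "n_modes"))
  seeds <- matrix(child_seeds(seed, 2 * length(values) * n_reps), ncol = 2)
  rows <- list()
  k <- 0L
  for (v in values) {
    for (r in seq_len(n_reps)) {
      k <- k + 1L
      x <- build_model_signal(model, parameter, v, seeds[k, 1])
      ev <- eval_methods_at_pair(x, grid, methods, n_surrogates,
                                 seeds[k, 2], ...)
      for (m in methods)
        rows[[length(rows) + 1L]] <- data.frame(
          value = v, rep = r, method = m, pac = ev[[m]]$value,
          detected = isTRUE(ev[[m]]$detected),
          label = if (is.null(ev[[m]]$label)) NA_character_ else ev[[m]]$label,
          stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("pac_sweep", class(out))
  attr(out, "model") <- model
  attr(out, "parameter") <- parameter
  out
}

#' Summarise a sweep
#'
#' Per (value, method): mean PAC normalised by the method's maximum across
#' the sweep, SEM of the normalised values, detection percentage, and for
#' eMI the Reliable share among detections.
#'
#' @param sweep result of [run_sweep()].
#' @return data frame with columns `value`, `method`, `mean_pac_norm`,
#'   `sem`, `detection_pct`, `reliable_pct`.
#' @export
summarize_sweep <- function(sweep) {
  rows <- list()
  for (m in unique(sweep$method)) {
    sm <- sweep[sweep$method == m, ]
    norm <- max(abs(sm$pac), na.rm = TRUE)
    for (v in unique(sm$value)) {
      sv <- sm[sm$value == v, ]
      pac <- sv$pac / norm
      det <- sv$detected
      rel <- if (m == "emi" && any(det))
        100 * mean(sv$label[det] == "Reliable", na.rm = TRUE) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        value = v, method = m,
        mean_pac_norm = mean(pac, na.rm = TRUE),
        sem = stats::sd(pac, na.rm = TRUE) / sqrt(sum(!is.na(pac))),
        detection_pct = 100 * mean(det),
        reliable_pct = rel)
    }
  }
  do.call(rbind, rows)
}

#' Collated time evolution of Reliable coupling across epochs
#'
#' For each epoch and each amplitude frequency, takes the maximum over
#' phase frequencies of the centred eMI values that are significant,
#' labeled Reliable, and pass a pooled Benjamini-Hochberg FDR correction at
#' level `q`; all other entries are 0.
#'
#' @param results list of `emi_pac` objects sharing one grid.
#' @param q FDR level.
#' @return matrix `f_A x epochs` of Reliable PAC maxima (class
#'   `pac_evolution`, with the `f_A` axis as attribute).
#' @export
collate_epochs <- function(results, q = 0.05) {
  stopifnot(length(results) >= 1)
  g0 <- results[[1]]$grid
  for (r in results)
    if (!identical(r$grid, g0)) stop("epochs use different grids")
  fdr_masks <- fdr_combine(lapply(results, function(r) r$P_vals), q)
  out <- matrix(0, length(g0$f_A), length(results))
  for (e in seq_along(results)) {
    r <- results[[e]]
    keep <- r$mask & fdr_masks[[e]] &
      !is.na(r$label_matrix) & r$label_matrix == "Reliable"
    vals <- r$values
    vals[!keep] <- NA_real_
    col <- suppressWarnings(apply(vals, 2, max, na.rm = TRUE))
    col[!is.finite(col)] <- 0
    out[, e] <- col
  }
  structure(out, f_A = g0$f_A, class = c("pac_evolution", "matrix"))
}
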