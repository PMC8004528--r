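# Significance machinery: extreme-value thresholds over the whole
# comodulogram, empirical percentiles, the phase-bin rejection rule, and
# FDR combination across epochs.

#' Extreme-value significance threshold for a comodulogram
#'
#' Takes the maximum of each surrogate comodulogram; the `p_C` percentile of
#' these maxima is the family-wise threshold. Values exceeding it are less
#' than `1 - p_C/100` likely under the no-coupling null. Percentiles use
#' linear interpolation between order statistics; the per-value empirical
#' percentile `P_vals` is computed with the finite-surrogate correction
#' `p = (1 + #{max >= v}) / (N + 1)`, so p-values are floored at
#' `1 / (N + 1)`.
#'
#' @param values original comodulogram matrix (may contain `NA`).
#' @param surrogates either a numeric vector of per-surrogate maxima or a
#'   list of surrogate comodulogram matrices (maxima are then taken here).
#' @param p_C percentile (default 95).
#' @return list with `threshold`, `mask` (`values > threshold`), `P_vals`
#'   (percentiles in `[0, 100]`), `surr_max` and `p_C`.
#' @export
extreme_value_threshold <- function(values, surrogates, p_C = 95) {
  surr_max <- if (is.list(surrogates))
    vapply(surrogates, function(m) max(m, na.rm = TRUE), numeric(1))
  else as.numeric(surrogates)
  n_s <- length(surr_max)
  if (n_s < 20)
    stop(sprintf("%d surrogates are too few for a %g-th percentile threshold",
                 n_s, p_C))
  thr <- pctile(surr_max, p_C)
  values <- as.matrix(values)
  mask <- !is.na(values) & values > thr
  P_vals <- matrix(NA_real_, nrow(values), ncol(values))
  ok <- !is.na(values)
  P_vals[ok] <- vapply(values[ok], function(v)
    100 * (1 - (1 + sum(surr_max >= v)) / (n_s + 1)), numeric(1))
  list(threshold = thr, mask = mask, P_vals = P_vals, surr_max = surr_max,
       p_C = p_C)
}

#' Phase-bin rejection rule
#'
#' A significant pair is kept only when its amplitude-over-phase
#' distribution exceeds the per-pair surrogate bin threshold in at least one
#' bin; otherwise the augmentation is not localised in phase and the pair is
#' rejected. Idempotent.
#'
#' @param mask logical matrix of significant pairs.
#' @param pd a `phase_distribution` (see [phase_distributions()]).
#' @return logical matrix of the same shape.
#' @export
bin_threshold_filter <- function(mask, pd) {
  stopifnot(inherits(pd, "phase_distribution"))
  stopifnot(all(dim(mask) == dim(pd$th)))
  any_over <- apply(sweep(pd$P, c(1, 2), pd$th, ">"), c(1, 2), any)
  mask & !is.na(any_over) & any_over
}

#' Benjamini-Hochberg FDR across epochs
#'
#' Converts the per-pair empirical percentiles of each epoch into p-values
#' (`1 - P_val/100`), pools them across epochs and pairs, applies the
#' Benjamini-Hochberg step-up procedure at level `q`, and returns per-epoch
#' rejection masks.
#'
#' @param P_vals_list list of `P_vals` matrices, one per epoch (may contain
#'   `NA` for unanalysed pairs).
#' @param q FDR level (default 0.05).
#' @return list of logical matrices, one per epoch.
#' @export
fdr_combine <- function(P_vals_list, q = 0.05) {
  stopifnot(length(P_vals_list) >= 1)
  p_all <- unlist(lapply(P_vals_list, function(m) 1 - as.numeric(m) / 100))
  adj <- stats::p.adjust(p_all, method = "BH")
  rej <- !is.na(adj) & adj <= q
  out <- vector("list", length(P_vals_list))
  pos <- 0L
  for (i in seq_along(P_vals_list)) {
    m <- P_vals_list[[i]]
    k <- length(m)
    out[[i]] <- matrix(rej[pos + seq_len(k)], nrow(m), ncol(m))
    pos <- pos + k
  }
  out
}
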