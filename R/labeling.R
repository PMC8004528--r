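# Region extraction from the significance mask and the Reliable/Ambiguous
# origin heuristic: a coupling is Reliable when the comodulogram maximum is
# congruent (within the wavelet frequency resolution) with a proper peak of
# the section spectra; harmonic chains with an Ambiguous base are relabeled.

#' Connected regions of a significance mask
#'
#' 8-connected components (diagonal neighbours merge) of the logical mask,
#' ordered by (minimum row, minimum column).
#'
#' @param mask logical matrix (`NA` treated as `FALSE`).
#' @return list of regions, each a list with `id` and `cells` (two-column
#'   matrix of row/column indices).
#' @export
extract_regions <- function(mask) {
  mask[is.na(mask)] <- FALSE
  cells <- which(mask, arr.ind = TRUE)
  if (nrow(cells) == 0) return(list())
  key <- function(i, j) paste(i, j)
  idx <- stats::setNames(seq_len(nrow(cells)), key(cells[, 1], cells[, 2]))
  edges <- integer()
  offs <- expand.grid(di = -1:1, dj = -1:1)
  offs <- offs[!(offs$di == 0 & offs$dj == 0), ]
  for (k in seq_len(nrow(cells))) {
    ni <- cells[k, 1] + offs$di
    nj <- cells[k, 2] + offs$dj
    nb <- idx[key(ni, nj)]
    nb <- nb[!is.na(nb) & nb > k]
    if (length(nb)) edges <- c(edges, rbind(k, nb))
  }
  g <- igraph::make_graph(edges = edges, n = nrow(cells), directed = FALSE)
  comp <- igraph::components(g)$membership
  regions <- lapply(unique(comp), function(cid) {
    cc <- cells[comp == cid, , drop = FALSE]
    list(cells = unname(cc))
  })
  ord <- order(vapply(regions, function(r) min(r$cells[, 1]), numeric(1)),
               vapply(regions, function(r) min(r$cells[, 2]), numeric(1)))
  regions <- regions[ord]
  for (i in seq_along(regions)) regions[[i]]$id <- i
  regions
}

#' Choose between average spectrum and spectrum of the average
#'
#' For each spectrum, sums its power over the frequencies of the search set
#' where it exceeds the other spectrum; the spectrum with the larger sum is
#' used for the peak search. Ties go to the average spectrum `AS`.
#'
#' @param AS,SA numeric spectra on a common frequency axis.
#' @param freq the common frequency axis (Hz).
#' @param f_A_M logical vector or index set selecting the search
#'   frequencies.
#' @return `"AS"` or `"SA"`.
#' @export
choose_spectrum <- function(AS, SA, freq, f_A_M) {
  sel <- if (is.logical(f_A_M)) which(f_A_M) else f_A_M
  s_as <- sum(AS[sel][AS[sel] > SA[sel]])
  s_sa <- sum(SA[sel][SA[sel] > AS[sel]])
  if (s_sa > s_as) "SA" else "AS"
}

#' Locate a proper spectral peak within a search set
#'
#' Finds the maximum power within the search frequencies (ties broken toward
#' the lower frequency) and accepts it only when it is a local maximum of
#' the full spectrum with strictly lower neighbours on both sides; a maximum
#' sitting on a rising slope or at the spectrum edge yields no proper peak.
#'
#' @param spectrum numeric power spectrum.
#' @param freq its frequency axis (Hz).
#' @param f_A_M logical vector or index set of search frequencies.
#' @return the peak frequency (Hz), or `NA_real_` when no proper peak
#'   exists.
#' @export
find_spectral_peak <- function(spectrum, freq, f_A_M) {
  sel <- if (is.logical(f_A_M)) which(f_A_M) else f_A_M
  if (!length(sel)) return(NA_real_)
  best <- sel[which.max(spectrum[sel])]  # which.max takes the first = lowest f
  n <- length(spectrum)
  if (best <= 1 || best >= n) return(NA_real_)
  if (spectrum[best] > spectrum[best - 1] && spectrum[best] > spectrum[best + 1])
    freq[best]
  else NA_real_
}

# per-column labeling of one region; returns the audit table
label_region_columns <- function(region, comod, spectra_list, grid, w) {
  rows <- sort(unique(region$cells[, 1]))
  span_A <- range(grid$f_A[region$cells[, 2]])
  audit <- data.frame(f_P = grid$f_P[rows], f_A_max = NA_real_,
                      delta = NA_real_, f_A_MAX = NA_real_,
                      spectrum = NA_character_, reliable = FALSE,
                      note = "", stringsAsFactors = FALSE)
  for (r in seq_along(rows)) {
    i <- rows[r]
    cols <- region$cells[region$cells[, 1] == i, 2]
    f_A_max <- grid$f_A[cols[which.max(comod[i, cols])]]
    audit$f_A_max[r] <- f_A_max
    if (f_A_max == grid$f_A[1]) {
      audit$note[r] <- "comodulogram maximum at lower f_A edge"
      warning(sprintf(
        "f_P = %g Hz: comodulogram maximum sits on the lower f_A edge; %s",
        grid$f_P[i], "labeling this column Ambiguous"), call. = FALSE)
      next
    }
    delta <- wavelet_fwhm_freq(f_A_max, w)
    audit$delta[r] <- delta
    sp <- spectra_list[[i]]
    if (is.null(sp)) { audit$note[r] <- "no section spectra"; next }
    in_M <- (sp$freq >= span_A[1] & sp$freq <= span_A[2]) |
      (sp$freq >= f_A_max - delta / 2 & sp$freq <= f_A_max + delta / 2)
    if (!any(in_M)) { audit$note[r] <- "search set empty"; next }
    tag <- choose_spectrum(sp$AS, sp$SA, sp$freq, in_M)
    audit$spectrum[r] <- tag
    spec <- if (tag == "AS") sp$AS else sp$SA
    f_A_MAX <- find_spectral_peak(spec, sp$freq, in_M)
    audit$f_A_MAX[r] <- f_A_MAX
    if (is.na(f_A_MAX)) { audit$note[r] <- "no proper peak"; next }
    audit$reliable[r] <- f_A_MAX >= f_A_max - delta / 2 &&
      f_A_MAX <= f_A_max + delta / 2
  }
  audit
}

#' Assign the Reliable/Ambiguous label to a region
#'
#' For every phase-frequency column of the region: the comodulogram maximum
#' `f_A^max` is located (a maximum on the lower edge of the `f_A` range is
#' an uncertain situation and makes the column Ambiguous with a warning);
#' the wavelet FWHM at `f_A^max` defines the congruence interval; the search
#' set is the union of the region's `f_A` span and that interval; the more
#' pronounced of the two section spectra is searched for a proper peak; the
#' column is Reliable when the peak lies within the congruence interval.
#' The region is Reliable when at least one of its columns is.
#'
#' @param region a region from [extract_regions()].
#' @param comod the centred comodulogram matrix.
#' @param spectra_list per-`f_P` list of `section_spectra` (or `NULL`).
#' @param grid a [pac_grid()].
#' @param w Morlet wavenumber used for the map.
#' @return the region with `label` (`"Reliable"` or `"Ambiguous"`) and a
#'   per-column `audit` data frame added.
#' @export
assign_label <- function(region, comod, spectra_list, grid, w) {
  audit <- label_region_columns(region, comod, spectra_list, grid, w)
  region$audit <- audit
  region$label <- if (any(audit$reliable)) "Reliable" else "Ambiguous"
  # centre frequency used by the harmonic-chain test
  imax <- which.max(comod[region$cells])
  region$center_f_P <- grid$f_P[region$cells[imax, 1]]
  region
}

#' Propagate Ambiguous labels along harmonic chains
#'
#' When the centre phase frequencies of regions form an approximate
#' integer-multiple chain (tolerance `tol`) whose base region is Ambiguous,
#' the harmonics are relabeled Ambiguous too. Monotone: labels only move
#' from Reliable to Ambiguous.
#'
#' @param regions list of labeled regions (see [assign_label()]).
#' @param tol frequency tolerance in Hz (typically `delta_f_P`).
#' @return the relabeled region list.
#' @export
propagate_harmonics <- function(regions, tol) {
  if (length(regions) < 2) return(regions)
  repeat {
    changed <- FALSE
    for (i in seq_along(regions)) {
      if (regions[[i]]$label != "Ambiguous") next
      base <- regions[[i]]$center_f_P
      for (j in seq_along(regions)) {
        if (j == i || regions[[j]]$label == "Ambiguous") next
        k <- round(regions[[j]]$center_f_P / base)
        if (k >= 2 && abs(regions[[j]]$center_f_P - k * base) < tol) {
          regions[[j]]$label <- "Ambiguous"
          regions[[j]]$harmonic_of <- regions[[i]]$id
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  regions
}

#' Phase histogram of a coupling region
#'
#' Mean of the per-pair phase-bin distributions over the member pairs of a
#' region; sums to 1.
#'
#' @param region a region from [extract_regions()].
#' @param pd a `phase_distribution`.
#' @return numeric vector of length `pd$J`.
#' @export
region_phase_histogram <- function(region, pd) {
  stopifnot(inherits(pd, "phase_distribution"))
  cells <- region$cells
  h <- numeric(pd$J)
  for (k in seq_len(nrow(cells)))
    h <- h + pd$P[cells[k, 1], cells[k, 2], ]
  h / nrow(cells)
}

# pipeline glue: regions + labels + histograms + cellwise label matrix
label_regions <- function(mask, comod, spectra_list, grid, w, pd) {
  regions <- extract_regions(mask)
  regions <- lapply(regions, assign_label, comod = comod,
                    spectra_list = spectra_list, grid = grid, w = w)
  regions <- propagate_harmonics(regions, tol = grid$delta_f_P)
  lm <- matrix(NA_character_, nrow(mask), ncol(mask))
  for (i in seq_along(regions)) {
    r <- regions[[i]]
    regions[[i]]$histogram <- if (!anyNA(pd$P[r$cells[1, 1], r$cells[1, 2], ]))
      region_phase_histogram(r, pd) else rep(NA_real_, pd$J)
    lm[r$cells] <- r$label
  }
  list(regions = regions, label_matrix = lm)
}
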