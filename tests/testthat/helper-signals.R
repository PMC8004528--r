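# Shared fixtures and independent oracles used across test files.

# small deterministic grid used by most pipeline tests
test_grid <- function() pac_grid(seq(2, 10, 1), seq(40, 120, 5))

# naive, loop-based evaluation of the dPAC sum (independent oracle)
dpac_naive <- function(phase, amplitude) {
  n <- length(phase)
  re <- im <- 0
  for (i in seq_len(n)) {
    re <- re + amplitude[i] * cos(phase[i])
    im <- im + amplitude[i] * sin(phase[i])
  }
  sqrt(re^2 + im^2) / (sqrt(n) * sqrt(sum(amplitude^2)))
}

# naive, loop-based MI (independent oracle): explicit binning, mean per bin,
# normalisation, KL distance
mi_naive <- function(phase, amplitude, J = 18) {
  edges <- seq(-pi, pi, length.out = J + 1)
  means <- numeric(J)
  for (j in seq_len(J)) {
    inb <- phase >= edges[j] & (phase < edges[j + 1] | (j == J & phase <= pi))
    means[j] <- if (any(inb)) mean(amplitude[inb]) else 0
  }
  P <- means / sum(means)
  kl <- 0
  for (j in seq_len(J)) if (P[j] > 0) kl <- kl + P[j] * log(P[j])
  (log(J) + kl) / log(J)
}

# brute-force flood fill (4/8-connectivity) for region extraction oracle
flood_fill_components <- function(mask) {
  mask[is.na(mask)] <- FALSE
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (!mask[i, j] || lab[i, j] > 0) next
    cur <- cur + 1L
    stack <- list(c(i, j))
    lab[i, j] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        ni <- p[1] + di; nj <- p[2] + dj
        if (ni >= 1 && ni <= nrow(mask) && nj >= 1 && nj <= ncol(mask) &&
            mask[ni, nj] && lab[ni, nj] == 0) {
          lab[ni, nj] <- cur
          stack[[length(stack) + 1L]] <- c(ni, nj)
        }
      }
    }
  }
  lab
}

# count of complete low-frequency cycles by zero-crossing enumeration of the
# clean sine (independent of the generator's internals)
cycle_count_zero_cross <- function(f_P, duration, fs) {
  t <- (0:(round(duration * fs) - 1)) / fs
  s <- sin(2 * pi * f_P * t)
  up <- which(s[-length(s)] < 0 & s[-1] >= 0)
  length(up)
}
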