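// Hot loops of the comodulogram construction: amplitude-over-phase-bin
// accumulation (MI) and complex mean-vector sums (dPAC), evaluated for
// every phase series against every amplitude series in one call.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix mi_cols_batch(NumericMatrix phase, NumericMatrix amp, int J) {
  const int n = phase.nrow(), nP = phase.ncol(), nA = amp.ncol();
  if (amp.nrow() != n) stop("phase and amplitude lengths differ");
  NumericMatrix out(nP, nA);
  std::vector<double> sums(J), counts(J);
  // phase is continuous, so bins come in runs; summing per run removes the
  // accumulator dependency and lets the inner loop vectorize
  std::vector<int> run_start, run_bin;
  const double logJ = std::log((double)J);
  for (int p = 0; p < nP; ++p) {
    std::fill(counts.begin(), counts.end(), 0.0);
    run_start.clear(); run_bin.clear();
    int prev = -1;
    for (int i = 0; i < n; ++i) {
      int b = (int)std::floor((phase(i, p) + M_PI) / (2.0 * M_PI) * J);
      if (b < 0) b = 0;
      if (b >= J) b = J - 1;
      counts[b] += 1.0;
      if (b != prev) { run_start.push_back(i); run_bin.push_back(b); prev = b; }
    }
    run_start.push_back(n);
    const int nr = (int)run_bin.size();
    for (int a = 0; a < nA; ++a) {
      std::fill(sums.begin(), sums.end(), 0.0);
      const double *col = &amp(0, a);
      for (int r = 0; r < nr; ++r) {
        double acc = 0.0;
        for (int i = run_start[r]; i < run_start[r + 1]; ++i) acc += col[i];
        sums[run_bin[r]] += acc;
      }
      double tot = 0.0;
      for (int j = 0; j < J; ++j) {
        if (counts[j] > 0) sums[j] /= counts[j];
        tot += sums[j];
      }
      double kl = 0.0;
      for (int j = 0; j < J; ++j) {
        double P = sums[j] / tot;
        if (P > 0) kl += P * std::log(P);
      }
      out(p, a) = (logJ + kl) / logJ;
    }
  }
  return out;
}

// dPAC for unit phasors given as separate real/imaginary matrices (avoids
// recomputing sin/cos when the phasors come from an analytic signal)
// [[Rcpp::export]]
NumericMatrix dpac_cols_batch(NumericMatrix pre, NumericMatrix pim,
                              NumericMatrix amp) {
  const int n = pre.nrow(), nP = pre.ncol(), nA = amp.ncol();
  if (amp.nrow() != n || pim.nrow() != n || pim.ncol() != nP)
    stop("phasor and amplitude dimensions differ");
  NumericMatrix out(nP, nA);
  std::vector<double> a2(nA);
  for (int a = 0; a < nA; ++a) {
    double s = 0.0;
    const double *col = &amp(0, a);
    for (int i = 0; i < n; ++i) s += col[i] * col[i];
    a2[a] = std::sqrt((double)n) * std::sqrt(s);
  }
  for (int p = 0; p < nP; ++p) {
    const double *cs = &pre(0, p), *sn = &pim(0, p);
    for (int a = 0; a < nA; ++a) {
      double re = 0.0, im = 0.0;
      const double *col = &amp(0, a);
      for (int i = 0; i < n; ++i) {
        re += col[i] * cs[i];
        im += col[i] * sn[i];
      }
      out(p, a) = std::sqrt(re * re + im * im) / a2[a];
    }
  }
  return out;
}
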