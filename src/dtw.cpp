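#include <Rcpp.h>
using namespace Rcpp;

// Banded dynamic-time-warping alignment cost between two feature
// trajectories (rows = frames, columns = features; both already scaled).
// mode 0: full alignment, Sakoe-Chiba band, cost normalized by path length.
// mode 1: open-end subsequence alignment of A (query) inside B; start and
//         end are free in B, cost normalized by the number of A frames.
// [[Rcpp::export]]
double dtw_cost_cpp(NumericMatrix A, NumericMatrix B, double band_frac,
                    int open_end) {
  const int n = A.nrow(), m = B.nrow(), k = A.ncol();
  const double INF = std::numeric_limits<double>::infinity();
  int band = (int)std::ceil(band_frac * std::max(n, m));
  if (band < std::abs(n - m) + 1) band = std::abs(n - m) + 1;

  std::vector<double> prev(m + 1, INF), cur(m + 1, INF);
  std::vector<double> prevL(m + 1, 0), curL(m + 1, 0);
  if (open_end) {
    for (int j = 0; j <= m; ++j) prev[j] = 0.0;  // free start in B
  } else {
    prev[0] = 0.0;
  }
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), INF);
    int jlo = 1, jhi = m;
    if (!open_end) {
      // band around the scaled diagonal
      double c = (double)i * m / n;
      jlo = std::max(1, (int)std::floor(c) - band);
      jhi = std::min(m, (int)std::ceil(c) + band);
    }
    for (int j = jlo; j <= jhi; ++j) {
      double d = 0.0;
      for (int t = 0; t < k; ++t) {
        double diff = A(i - 1, t) - B(j - 1, t);
        d += diff * diff;
      }
      d = std::sqrt(d);
      double best = prev[j - 1]; double bl = prevL[j - 1];
      if (prev[j] < best) { best = prev[j]; bl = prevL[j]; }
      if (cur[j - 1] < best) { best = cur[j - 1]; bl = curL[j - 1]; }
      if (best == INF) continue;
      cur[j] = best + d;
      curL[j] = bl + 1;
    }
    std::swap(prev, cur);
    std::swap(prevL, curL);
  }
  if (open_end) {
    double best = INF, bl = 1;
    for (int j = 1; j <= m; ++j) {
      if (prev[j] < best) { best = prev[j]; bl = prevL[j]; }
    }
    if (best == INF) return NA_REAL;
    return best / std::max(1.0, (double)n);
  }
  if (prev[m] == INF) return NA_REAL;
  return prev[m] / std::max(1.0, prevL[m]);
}
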