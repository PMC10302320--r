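#include <Rcpp.h>
using namespace Rcpp;

// Dynamic time warping distance between two numeric sequences.
// Local cost |a_i - b_j|; steps (1,0), (0,1), (1,1), unweighted; optional
// Sakoe-Chiba band given as a fraction of the longer sequence length
// (band >= 1 disables the constraint).
// [[Rcpp::export(name = ".dtw_cost")]]
double dtw_cost(NumericVector a, NumericVector b, double band) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  const double inf = R_PosInf;
  int w;
  if (band >= 1.0) {
    w = std::max(n, m);
  } else {
    w = (int)std::ceil(band * std::max(n, m));
    // band must at least cover the slope between corners
    w = std::max(w, std::abs(n - m));
  }
  std::vector<double> prev(m + 1, inf), cur(m + 1, inf);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), inf);
    int jlo = std::max(1, i - w), jhi = std::min(m, i + w);
    for (int j = jlo; j <= jhi; ++j) {
      double c = std::fabs(a[i - 1] - b[j - 1]);
      double best = prev[j - 1];              // diagonal
      if (prev[j] < best) best = prev[j];     // insertion
      if (cur[j - 1] < best) best = cur[j - 1]; // deletion
      cur[j] = c + best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}
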