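#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Band-constrained dynamic time warping.
//
// Squared-difference local cost, symmetric step pattern (diagonal, left,
// up), endpoints anchored at (1,1) and (n,m). Cells with |i - j| > band
// are infeasible; band < 0 means unconstrained. Returns the square root
// of the accumulated cost (no path-length normalization).
// [[Rcpp::export(name = ".dtw_band_cost")]]
double dtw_band_cost(NumericVector a, NumericVector b, int band) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty series");
  const double inf = std::numeric_limits<double>::infinity();
  if (band >= 0 && std::abs(n - m) > band)
    stop("band too narrow for the length difference");
  std::vector<double> prev(m + 1, inf), cur(m + 1, inf);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), inf);
    int jlo = 1, jhi = m;
    if (band >= 0) {
      jlo = std::max(1, i - band);
      jhi = std::min(m, i + band);
    }
    for (int j = jlo; j <= jhi; ++j) {
      double d = a[i - 1] - b[j - 1];
      double best = prev[j - 1];            // diagonal
      if (prev[j] < best) best = prev[j];   // up
      if (cur[j - 1] < best) best = cur[j - 1]; // left
      cur[j] = d * d + best;
    }
    std::swap(prev, cur);
  }
  double total = prev[m];
  if (!std::isfinite(total)) stop("band made the endpoint unreachable");
  return std::sqrt(total);
}
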