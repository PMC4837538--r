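// Banded pairwise r^2 with distance binning for LD-decay curves.
// Pairs with either genotype missing are excluded pairwise; pairs that are
// monomorphic among complete observations are skipped (undefined r^2).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// G: m x n dosage matrix (one chromosome), pos: bp positions (ascending),
// maxDist: maximum pair distance (bp), binW: bin width (bp).
// Returns per-bin sum of r^2 and pair counts; bin b covers
// ((b-1)*binW, b*binW].
// [[Rcpp::export]]
List ld_bins_cpp(IntegerMatrix G, NumericVector pos, double maxDist, double binW) {
  const int m = G.nrow(), n = G.ncol();
  const int nb = (int)std::ceil(maxDist / binW);
  NumericVector sums(nb);
  IntegerVector counts(nb);
  const int* g = INTEGER(G);
  for (int i = 0; i < m; ++i) {
    for (int j = i + 1; j < m; ++j) {
      double dist = pos[j] - pos[i];
      if (dist > maxDist) break;
      const int* gi = g + (size_t)i;
      const int* gj = g + (size_t)j;
      double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
      int cnt = 0;
      for (int a = 0; a < n; ++a) {
        int xi = gi[(size_t)a * m], yj = gj[(size_t)a * m];
        if (xi == NA_INTEGER || yj == NA_INTEGER) continue;
        sx += xi; sy += yj;
        sxx += (double)xi * xi; syy += (double)yj * yj;
        sxy += (double)xi * yj;
        ++cnt;
      }
      if (cnt < 2) continue;
      double vx = cnt * sxx - sx * sx;
      double vy = cnt * syy - sy * sy;
      if (vx <= 0 || vy <= 0) continue;  // monomorphic among complete pairs
      double cov = cnt * sxy - sx * sy;
      double r2 = (cov * cov) / (vx * vy);
      int b = (int)std::ceil(dist / binW) - 1;
      if (b < 0) b = 0;
      if (b >= nb) continue;
      sums[b] += r2;
      counts[b] += 1;
    }
  }
  return List::create(_["sum"] = sums, _["count"] = counts);
}
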