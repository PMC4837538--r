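// Per-SNP linear mixed-model Wald scan on the spectral decomposition of the
// relationship matrix. For each SNP the variance ratio lambda =
// sigma2_u / sigma2_e is re-optimised by profiled REML over a log-spaced
// grid with parabolic refinement (exact-LMM style), then beta, its standard
// error and the 1-df Wald chi-square p-value are computed by weighted least
// squares in the rotated coordinates.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

// Profiled REML log-likelihood (up to a constant) and GLS estimates for
// X = [x1, w] with weights wi = 1 / (lambda * d_i + 1).
struct Fit { double ll, beta, se, sigma2e; bool ok; };

inline Fit evalLambda(const double* wgt, double sumLog, int n,
                      const double* x1, const double* w, const double* y) {
  double a11 = 0, a12 = 0, a22 = 0, b1 = 0, b2 = 0, yy = 0;
  for (int i = 0; i < n; ++i) {
    double wi = wgt[i];
    a11 += wi * x1[i] * x1[i];
    a12 += wi * x1[i] * w[i];
    a22 += wi * w[i] * w[i];
    b1 += wi * x1[i] * y[i];
    b2 += wi * w[i] * y[i];
    yy += wi * y[i] * y[i];
  }
  Fit f; f.ok = true;
  double det = a11 * a22 - a12 * a12;
  if (det <= 1e-10 * a11 * a22 || det <= 0) { f.ok = false; f.ll = -INFINITY; return f; }
  double beta1 = (a22 * b1 - a12 * b2) / det;
  double beta2 = (a11 * b2 - a12 * b1) / det;
  double rss = yy - b1 * beta1 - b2 * beta2;
  if (rss <= 0) rss = 1e-12;
  int p = 2;
  f.sigma2e = rss / (n - p);
  f.beta = beta2;
  f.se = std::sqrt(f.sigma2e * a11 / det);
  f.ll = -0.5 * (sumLog + (n - p) * std::log(rss) + std::log(det));
  return f;
}

} // namespace

// UtW: rotated SNP dosage columns (n x m); Ut1, Uty: rotated intercept and
// phenotype; d: eigenvalues of A; lambdaGrid: candidate variance ratios
// (log-spaced). lambdaFixed >= 0 skips the per-SNP optimisation.
// skip: 1-based index of a column to skip (0 = none); mono: logical vector
// flagging monomorphic SNPs (returned as NA).
// [[Rcpp::export]]
List snp_scan_cpp(NumericMatrix UtW, NumericVector Ut1, NumericVector Uty,
                  NumericVector d, NumericVector lambdaGrid,
                  double lambdaFixed, LogicalVector mono) {
  const int n = UtW.nrow(), m = UtW.ncol();
  const int G = lambdaGrid.size();
  const double* x1 = REAL(Ut1);
  const double* y = REAL(Uty);

  // weight grid and shared log-determinant terms
  std::vector<double> wgt((size_t)G * n), sumLog(G);
  for (int gidx = 0; gidx < G; ++gidx) {
    double lam = lambdaGrid[gidx];
    double sl = 0.0;
    double* wg = &wgt[(size_t)gidx * n];
    for (int i = 0; i < n; ++i) {
      double v = lam * d[i] + 1.0;
      wg[i] = 1.0 / v;
      sl += std::log(v);
    }
    sumLog[gidx] = sl;
  }
  std::vector<double> wfix(n);
  double slfix = 0.0;
  if (lambdaFixed >= 0) {
    for (int i = 0; i < n; ++i) {
      double v = lambdaFixed * d[i] + 1.0;
      wfix[i] = 1.0 / v; slfix += std::log(v);
    }
  }

  NumericVector beta(m, NA_REAL), se(m, NA_REAL), pval(m, NA_REAL),
      lambda(m, NA_REAL), sig2(m, NA_REAL);
  for (int j = 0; j < m; ++j) {
    if (mono[j]) continue;
    const double* w = &UtW(0, j);
    Fit best; best.ll = -INFINITY; best.ok = false;
    double bestLam = NA_REAL;
    if (lambdaFixed >= 0) {
      best = evalLambda(wfix.data(), slfix, n, x1, w, y);
      bestLam = lambdaFixed;
    } else {
      int bi = -1;
      std::vector<double> lls(G);
      for (int gidx = 0; gidx < G; ++gidx) {
        Fit f = evalLambda(&wgt[(size_t)gidx * n], sumLog[gidx], n, x1, w, y);
        lls[gidx] = f.ll;
        if (f.ok && f.ll > best.ll) { best = f; bi = gidx; }
      }
      if (bi < 0) continue;
      bestLam = lambdaGrid[bi];
      // parabolic refinement in log-lambda using the grid neighbours
      if (bi > 0 && bi < G - 1 && std::isfinite(lls[bi - 1]) && std::isfinite(lls[bi + 1])) {
        double l0 = std::log(lambdaGrid[bi - 1]), l1 = std::log(lambdaGrid[bi]),
               l2 = std::log(lambdaGrid[bi + 1]);
        double f0 = lls[bi - 1], f1 = lls[bi], f2 = lls[bi + 1];
        double denom = (f0 - 2 * f1 + f2);
        if (denom < -1e-12) {
          double lv = l1 - 0.5 * (l2 - l0) / 2.0 * (f2 - f0) / denom;
          if (lv > l0 && lv < l2) {
            double lam = std::exp(lv);
            std::vector<double> wv(n);
            double sl = 0.0;
            for (int i = 0; i < n; ++i) {
              double v = lam * d[i] + 1.0;
              wv[i] = 1.0 / v; sl += std::log(v);
            }
            Fit f = evalLambda(wv.data(), sl, n, x1, w, y);
            if (f.ok && f.ll > best.ll) { best = f; bestLam = lam; }
          }
        }
      }
    }
    if (!best.ok) continue;
    beta[j] = best.beta;
    se[j] = best.se;
    lambda[j] = bestLam;
    sig2[j] = best.sigma2e;
    double wald = (best.beta / best.se) * (best.beta / best.se);
    pval[j] = R::pchisq(wald, 1.0, 0, 0);  // upper tail
  }
  return List::create(_["beta"] = beta, _["se"] = se, _["p"] = pval,
                      _["lambda"] = lambda, _["sigma2e"] = sig2);
}
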