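// Haplotype-cluster hidden Markov model (fastPHASE-style) for unphased
// genotypes: EM over locus-specific emission probabilities, posterior
// ancestral dosages, and genotype imputation.
//
// The diploid chain is the product of two gamete chains over K ancestral
// states with factorising transitions
//   t(a -> c) = (1 - J) 1{a == c} + J * alpha_c,
// which keeps every forward/backward update at O(K^2) per locus.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct HmmData {
  int m, n, K;
  const int* G;            // m x n genotypes, NA_INTEGER for missing
  std::vector<double> jump;    // per-interval jump probability (index 1..m-1)
  std::vector<int> blockStart; // chromosome block starts, terminated by m
};

// emission value for genotype g given theta row th (length K), into E (K x K)
inline void emission(const double* th, int g, int K, std::vector<double>& E) {
  for (int b = 0; b < K; ++b) {
    double tb = th[b];
    for (int a = 0; a < K; ++a) {
      double ta = th[a];
      double e;
      if (g == 2) e = ta * tb;
      else if (g == 1) e = ta * (1.0 - tb) + (1.0 - ta) * tb;
      else e = (1.0 - ta) * (1.0 - tb);
      E[a + K * b] = e;
    }
  }
}

} // namespace

// One full E-step (and optional output pass) for all animals.
// Accumulates Anum/Aden for the theta update and returns the log-likelihood.
// If H is non-null, fills posterior state dosages (n x K x m), and imputes
// missing genotypes into Gimp (posterior-mode genotype).
static double estep(const HmmData& D, const std::vector<double>& theta,
                    const std::vector<double>& alpha,
                    std::vector<double>* Anum, std::vector<double>* Aden,
                    double* H, int* Gimp, bool hardAssign = false) {
  const int m = D.m, n = D.n, K = D.K;
  const int KK = K * K;
  std::vector<double> fstore((size_t)m * KK);
  std::vector<double> b(KK), g(KK), E(KK), gam(KK);
  double ll = 0.0;

  for (int i = 0; i < n; ++i) {
    const int* gi = D.G + (size_t)m * i;
    for (size_t blk = 0; blk + 1 < D.blockStart.size(); ++blk) {
      int s = D.blockStart[blk], e = D.blockStart[blk + 1];
      // ---- forward, scaled
      for (int j = s; j < e; ++j) {
        double* f = &fstore[(size_t)j * KK];
        if (j == s) {
          for (int bb = 0; bb < K; ++bb)
            for (int aa = 0; aa < K; ++aa)
              f[aa + K * bb] = alpha[aa] * alpha[bb];
        } else {
          const double* fp = &fstore[(size_t)(j - 1) * KK];
          double J = D.jump[j];
          double c1 = (1.0 - J) * (1.0 - J), c2 = (1.0 - J) * J, c3 = J * J;
          // row sums R_a, col sums C_b of fp (fp sums to 1)
          std::vector<double> R(K, 0.0), C(K, 0.0);
          for (int bb = 0; bb < K; ++bb)
            for (int aa = 0; aa < K; ++aa) {
              double v = fp[aa + K * bb];
              R[aa] += v; C[bb] += v;
            }
          for (int bb = 0; bb < K; ++bb)
            for (int aa = 0; aa < K; ++aa)
              f[aa + K * bb] = c1 * fp[aa + K * bb]
                + c2 * (alpha[bb] * R[aa] + alpha[aa] * C[bb])
                + c3 * alpha[aa] * alpha[bb];
        }
        int gg = gi[j];
        if (gg != NA_INTEGER) {
          emission(&theta[(size_t)j * K], gg, K, E);
          for (int t = 0; t < KK; ++t) f[t] *= E[t];
        }
        double sc = 0.0;
        for (int t = 0; t < KK; ++t) sc += f[t];
        if (sc <= 0) sc = 1e-300;
        double inv = 1.0 / sc;
        // flush tiny cells to zero: avoids denormal arithmetic, which is
        // orders of magnitude slower and numerically irrelevant here
        for (int t = 0; t < KK; ++t) {
          f[t] *= inv;
          if (f[t] < 1e-150) f[t] = 0.0;
        }
        ll += std::log(sc);
      }
      // ---- backward + posteriors
      std::fill(b.begin(), b.end(), 1.0 / KK);
      for (int j = e - 1; j >= s; --j) {
        const double* f = &fstore[(size_t)j * KK];
        double sg = 0.0;
        for (int t = 0; t < KK; ++t) { gam[t] = f[t] * b[t]; sg += gam[t]; }
        double inv = 1.0 / sg;
        for (int t = 0; t < KK; ++t) gam[t] *= inv;

        int gg = gi[j];
        const double* th = &theta[(size_t)j * K];
        if (Anum != nullptr && gg != NA_INTEGER) {
          double* An = &(*Anum)[(size_t)j * K];
          double* Ad = &(*Aden)[(size_t)j * K];
          if (gg == 2 || gg == 0) {
            for (int bb = 0; bb < K; ++bb)
              for (int aa = 0; aa < K; ++aa) {
                double v = gam[aa + K * bb];
                Ad[aa] += v; Ad[bb] += v;
                if (gg == 2) { An[aa] += v; An[bb] += v; }
              }
          } else {  // het: split the single alt allele between the gametes
            for (int bb = 0; bb < K; ++bb) {
              double tb = th[bb];
              for (int aa = 0; aa < K; ++aa) {
                double ta = th[aa];
                double e1 = ta * (1.0 - tb);           // gamete 1 carries alt
                double e = e1 + (1.0 - ta) * tb;
                double w = (e > 0) ? e1 / e : 0.5;
                double v = gam[aa + K * bb];
                An[aa] += v * w; An[bb] += v * (1.0 - w);
                Ad[aa] += v; Ad[bb] += v;
              }
            }
          }
        }
        if (H != nullptr) {
          double* Hj = H + (size_t)n * K * j;
          if (hardAssign) {
            // posterior-mode pair: integer copy counts
            int best = 0;
            for (int t = 1; t < KK; ++t) if (gam[t] > gam[best]) best = t;
            Hj[i + (size_t)n * (best % K)] += 1.0;
            Hj[i + (size_t)n * (best / K)] += 1.0;
          } else {
            // posterior expected state copies: row + column marginals
            for (int bb = 0; bb < K; ++bb)
              for (int aa = 0; aa < K; ++aa) {
                double v = gam[aa + K * bb];
                Hj[i + (size_t)n * aa] += v;
                Hj[i + (size_t)n * bb] += v;
              }
          }
          if (Gimp != nullptr && gg == NA_INTEGER) {
            double p2 = 0.0, p1 = 0.0;
            for (int bb = 0; bb < K; ++bb) {
              double tb = th[bb];
              for (int aa = 0; aa < K; ++aa) {
                double ta = th[aa];
                double v = gam[aa + K * bb];
                p2 += v * ta * tb;
                p1 += v * (ta * (1.0 - tb) + (1.0 - ta) * tb);
              }
            }
            double p0 = 1.0 - p2 - p1;
            int best = 0; double pb = p0;
            if (p1 > pb) { best = 1; pb = p1; }
            if (p2 > pb) { best = 2; }
            Gimp[(size_t)m * i + j] = best;
          }
        }
        // ---- backward step to locus j-1
        if (j > s) {
          if (gg != NA_INTEGER) {
            emission(th, gg, K, E);
            for (int t = 0; t < KK; ++t) g[t] = E[t] * b[t];
          } else {
            for (int t = 0; t < KK; ++t) g[t] = b[t];
          }
          double J = D.jump[j];
          double c1 = (1.0 - J) * (1.0 - J), c2 = (1.0 - J) * J, c3 = J * J;
          std::vector<double> u(K, 0.0), v(K, 0.0);
          double w = 0.0;
          for (int bb = 0; bb < K; ++bb)
            for (int aa = 0; aa < K; ++aa) {
              double x = g[aa + K * bb];
              u[aa] += alpha[bb] * x;
              v[bb] += alpha[aa] * x;
              w += alpha[aa] * alpha[bb] * x;
            }
          double sb = 0.0;
          for (int bb = 0; bb < K; ++bb)
            for (int aa = 0; aa < K; ++aa) {
              double x = c1 * g[aa + K * bb] + c2 * (u[aa] + v[bb]) + c3 * w;
              b[aa + K * bb] = x; sb += x;
            }
          double inv2 = 1.0 / sb;
          for (int t = 0; t < KK; ++t) {
            b[t] *= inv2;
            if (b[t] < 1e-150) b[t] = 0.0;
          }
        }
      }
    }
  }
  return ll;
}

// [[Rcpp::export]]
List hmm_fit_cpp(IntegerMatrix G, NumericVector jump, IntegerVector blockStart,
                 NumericMatrix theta0, NumericVector alpha, int nIter,
                 bool computeH, bool impute, bool hardAssign) {
  HmmData D;
  D.m = G.nrow(); D.n = G.ncol(); D.K = theta0.ncol();
  D.G = INTEGER(G);
  D.jump.assign(jump.begin(), jump.end());
  D.blockStart.assign(blockStart.begin(), blockStart.end());
  const int m = D.m, n = D.n, K = D.K;

  std::vector<double> theta((size_t)m * K);
  for (int j = 0; j < m; ++j)
    for (int k = 0; k < K; ++k) theta[(size_t)j * K + k] = theta0(j, k);
  std::vector<double> a(alpha.begin(), alpha.end());

  std::vector<double> llTrace;
  std::vector<double> Anum, Aden;
  for (int it = 0; it < nIter; ++it) {
    Anum.assign((size_t)m * K, 0.0);
    Aden.assign((size_t)m * K, 0.0);
    double ll = estep(D, theta, a, &Anum, &Aden, nullptr, nullptr);
    llTrace.push_back(ll);
    const double eps = 1e-6;
    for (size_t t = 0; t < theta.size(); ++t)
      theta[t] = (Anum[t] + eps) / (Aden[t] + 2.0 * eps);
    Rcpp::checkUserInterrupt();
  }

  NumericVector H;
  IntegerMatrix Gimp;
  double llFinal;
  if (computeH || impute) {
    H = NumericVector((size_t)n * K * m);  // zero-initialised
    if (impute) Gimp = clone(G);
    llFinal = estep(D, theta, a, nullptr, nullptr, REAL(H),
                    impute ? INTEGER(Gimp) : nullptr, hardAssign);
    H.attr("dim") = IntegerVector::create(n, K, m);
  } else {
    llFinal = estep(D, theta, a, nullptr, nullptr, nullptr, nullptr);
  }
  llTrace.push_back(llFinal);

  NumericMatrix thetaOut(m, K);
  for (int j = 0; j < m; ++j)
    for (int k = 0; k < K; ++k) thetaOut(j, k) = theta[(size_t)j * K + k];

  return List::create(_["theta"] = thetaOut, _["logLik"] = wrap(llTrace),
                      _["H"] = H, _["imputed"] = Gimp);
}

// Invariants of B = H_i H_i' needed for closed-form permutation moments of
// the score statistic, per position: D1 = tr(B), D2 = sum diag(B)^2,
// SB = sum(B), C = sum(diag(B) * rowSums(B)), F2 = ||B||_F^2,
// P2 = sum(rowSums(B)^2).
// [[Rcpp::export]]
NumericMatrix perm_invariants_cpp(NumericVector H) {
  IntegerVector dm = H.attr("dim");
  int n = dm[0], K = dm[1], m = dm[2];
  NumericMatrix out(m, 6);
  std::vector<double> s(K), SS((size_t)K * K), rho(n), d(n);
  const double* h = REAL(H);
  for (int j = 0; j < m; ++j) {
    const double* Hj = h + (size_t)n * K * j;
    std::fill(s.begin(), s.end(), 0.0);
    std::fill(SS.begin(), SS.end(), 0.0);
    for (int k = 0; k < K; ++k) {
      const double* col = Hj + (size_t)n * k;
      double sk = 0.0;
      for (int i = 0; i < n; ++i) sk += col[i];
      s[k] = sk;
    }
    // d_i = ||h_i||^2, rho_i = h_i . s, SS = H'H
    std::fill(rho.begin(), rho.end(), 0.0);
    std::fill(d.begin(), d.end(), 0.0);
    for (int k = 0; k < K; ++k) {
      const double* ck = Hj + (size_t)n * k;
      for (int i = 0; i < n; ++i) {
        d[i] += ck[i] * ck[i];
        rho[i] += ck[i] * s[k];
      }
      for (int l = k; l < K; ++l) {
        const double* cl = Hj + (size_t)n * l;
        double acc = 0.0;
        for (int i = 0; i < n; ++i) acc += ck[i] * cl[i];
        SS[k + K * l] = acc; SS[l + K * k] = acc;
      }
    }
    double D1 = 0.0, F2 = 0.0, SB = 0.0, C = 0.0, D2 = 0.0, P2 = 0.0;
    for (int k = 0; k < K; ++k) {
      D1 += SS[k + K * k];
      SB += s[k] * s[k];
      for (int l = 0; l < K; ++l) F2 += SS[k + K * l] * SS[k + K * l];
    }
    for (int i = 0; i < n; ++i) {
      D2 += d[i] * d[i];
      C += d[i] * rho[i];
      P2 += rho[i] * rho[i];
    }
    out(j, 0) = D1; out(j, 1) = D2; out(j, 2) = SB;
    out(j, 3) = C; out(j, 4) = F2; out(j, 5) = P2;
  }
  colnames(out) = CharacterVector::create("D1", "D2", "SB", "C", "F2", "P2");
  return out;
}

// Score statistic T = 0.5 * ||H_i' r||^2 at every position.
// [[Rcpp::export]]
NumericVector hap_scan_T_cpp(NumericVector H, NumericVector r) {
  IntegerVector dm = H.attr("dim");
  int n = dm[0], K = dm[1], m = dm[2];
  NumericVector out(m);
  const double* h = REAL(H);
  const double* rr = REAL(r);
  for (int j = 0; j < m; ++j) {
    const double* Hj = h + (size_t)n * K * j;
    double acc = 0.0;
    for (int k = 0; k < K; ++k) {
      const double* ck = Hj + (size_t)n * k;
      double v = 0.0;
      for (int i = 0; i < n; ++i) v += ck[i] * rr[i];
      acc += v * v;
    }
    out[j] = 0.5 * acc;
  }
  return out;
}
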