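#include <Rcpp.h>
using namespace Rcpp;

// xorshift64: own PRNG so epoch ordering is identical across platforms
static inline uint64_t xs64(uint64_t &s) {
  s ^= s << 13; s ^= s >> 7; s ^= s << 17; return s;
}

// Dual coordinate descent for the L1-loss (hinge) linear SVM:
//   min_w 0.5 ||w||^2 + sum_i C_i max(0, 1 - y_i w'x_i)
// solved in the dual, one alpha_i at a time. Instances arrive as columns of
// a transposed sparse feature matrix (dgCMatrix slots), bias row included,
// so each coordinate update touches only the instance's nonzeros. Stops when
// the largest projected-gradient violation in an epoch falls below eps.
// [[Rcpp::export]]
List dcd_svm(IntegerVector Xt_p, IntegerVector Xt_i, NumericVector Xt_x,
             int n_feat, NumericVector y, NumericVector Ci,
             double eps, int max_epochs, double seed) {
  const int n = Xt_p.size() - 1;
  std::vector<double> w(n_feat, 0.0), alpha(n, 0.0), Qii(n);
  for (int i = 0; i < n; ++i) {
    double q = 0;
    for (int t = Xt_p[i]; t < Xt_p[i + 1]; ++t) q += Xt_x[t] * Xt_x[t];
    Qii[i] = q;
  }
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  uint64_t st = (uint64_t)seed * 2685821657736338717ULL + 1442695040888963407ULL;
  double viol = 0;
  int epoch;
  for (epoch = 1; epoch <= max_epochs; ++epoch) {
    for (int i = n - 1; i > 0; --i) {  // Fisher-Yates epoch permutation
      int j = (int)(xs64(st) % (uint64_t)(i + 1));
      std::swap(order[i], order[j]);
    }
    viol = 0;
    for (int s = 0; s < n; ++s) {
      const int i = order[s];
      if (Qii[i] <= 0) continue;       // zero vector: alpha stays 0
      double dot = 0;
      for (int t = Xt_p[i]; t < Xt_p[i + 1]; ++t) dot += w[Xt_i[t]] * Xt_x[t];
      const double G = y[i] * dot - 1.0;
      double PG = G;
      if (alpha[i] <= 0) PG = std::min(G, 0.0);
      else if (alpha[i] >= Ci[i]) PG = std::max(G, 0.0);
      if (std::fabs(PG) > viol) viol = std::fabs(PG);
      if (PG != 0.0) {
        const double a_old = alpha[i];
        const double a_new =
          std::min(std::max(a_old - G / Qii[i], 0.0), Ci[i]);
        alpha[i] = a_new;
        const double d = (a_new - a_old) * y[i];
        if (d != 0.0)
          for (int t = Xt_p[i]; t < Xt_p[i + 1]; ++t)
            w[Xt_i[t]] += d * Xt_x[t];
      }
    }
    if (viol < eps) break;
  }
  return List::create(_["w"] = w, _["alpha"] = alpha,
                      _["epochs"] = std::min(epoch, max_epochs),
                      _["violation"] = viol,
                      _["converged"] = viol < eps);
}
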