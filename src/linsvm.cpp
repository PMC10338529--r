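#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Dual coordinate descent for the binary L2-regularised L2-loss linear SVC
//   min_w 0.5 w'w + C * sum_i max(0, 1 - y_i w'x_i)^2
// solved in the dual: min 0.5 a'(Q + D)a - e'a, a_i >= 0, D_ii = 1/(2C),
// with the standard shrinking heuristic on the active set.  X is dense
// n x d (a bias column, if wanted, is appended by the caller and is
// regularised like any other coordinate).  Deterministic given `seed`.
//
// [[Rcpp::export]]
NumericVector l2svc_dcd(NumericMatrix X, NumericVector y, double C,
                        double eps, int max_iter, int seed) {
  const int n = X.nrow(), d = X.ncol();
  NumericVector w(d), alpha(n), qbar(n);
  const double D = 1.0 / (2.0 * C);

  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < d; ++j) s += X(i, j) * X(i, j);
    qbar[i] = s + D;
  }

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  int active = n;
  // private LCG so results do not depend on R's RNG state
  unsigned long long rng = (unsigned long long)(seed <= 0 ? 1 : seed);
  auto next_rng = [&rng]() {
    rng = rng * 6364136223846793005ULL + 1442695040888963407ULL;
    return (rng >> 33);
  };

  double PGmax_old = R_PosInf, PGmin_old = R_NegInf;
  for (int iter = 0; iter < max_iter; ++iter) {
    double PGmax_new = R_NegInf, PGmin_new = R_PosInf;
    // shuffle the active set
    for (int i = active - 1; i > 0; --i) {
      int j = (int)(next_rng() % (unsigned long long)(i + 1));
      std::swap(idx[i], idx[j]);
    }
    for (int k = 0; k < active; ++k) {
      const int i = idx[k];
      double s = 0.0;
      for (int j = 0; j < d; ++j) s += w[j] * X(i, j);
      const double G = y[i] * s - 1.0 + D * alpha[i];
      double PG = G;
      if (alpha[i] == 0.0) {
        if (G > PGmax_old) {          // shrink this coordinate
          active--;
          std::swap(idx[k], idx[active]);
          k--;
          continue;
        }
        if (G > 0.0) PG = 0.0;
      }
      if (PG > PGmax_new) PGmax_new = PG;
      if (PG < PGmin_new) PGmin_new = PG;
      if (std::fabs(PG) > 1e-12) {
        const double a_old = alpha[i];
        double a_new = a_old - G / qbar[i];
        if (a_new < 0.0) a_new = 0.0;
        alpha[i] = a_new;
        const double step = (a_new - a_old) * y[i];
        if (step != 0.0)
          for (int j = 0; j < d; ++j) w[j] += step * X(i, j);
      }
    }
    if (PGmax_new - PGmin_new <= eps) {
      if (active == n) break;
      // converged on the shrunken problem: re-activate and re-check
      active = n;
      PGmax_old = R_PosInf;
      PGmin_old = R_NegInf;
      continue;
    }
    PGmax_old = (PGmax_new <= 0.0) ? R_PosInf : PGmax_new;
    PGmin_old = (PGmin_new >= 0.0) ? R_NegInf : PGmin_new;
  }
  return w;
}

// Pointwise one-way ANOVA F statistics for curves: Y is n x T (rows = curves),
// g is a 0-based group index of length n with K groups.  Returns the T-vector
// of F values.  Used heavily inside the permutation loop of the SPM ANOVA.
//
// [[Rcpp::export]]
NumericVector pointwise_f(NumericMatrix Y, IntegerVector g, int K) {
  const int n = Y.nrow(), T = Y.ncol();
  std::vector<int> cnt(K, 0);
  for (int i = 0; i < n; ++i) cnt[g[i]]++;
  NumericVector F(T);
  std::vector<double> gs(K);
  for (int t = 0; t < T; ++t) {
    double tot = 0.0;
    std::fill(gs.begin(), gs.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      gs[g[i]] += Y(i, t);
      tot += Y(i, t);
    }
    const double gm = tot / n;
    double ssb = 0.0;
    for (int k = 0; k < K; ++k) {
      const double m = gs[k] / cnt[k];
      ssb += cnt[k] * (m - gm) * (m - gm);
    }
    double ssw = 0.0;
    for (int i = 0; i < n; ++i) {
      const double m = gs[g[i]] / cnt[g[i]];
      const double r = Y(i, t) - m;
      ssw += r * r;
    }
    const double dfb = K - 1, dfw = n - K;
    F[t] = (ssw <= 0.0) ? (ssb > 0.0 ? R_PosInf : 0.0)
                        : (ssb / dfb) / (ssw / dfw);
  }
  return F;
}
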