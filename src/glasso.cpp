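#include <Rcpp.h>
using namespace Rcpp;

// Cycling coordinate descent for 0.5 b'Vb - s'b + sum(r_k |b_k|).
// V is (p-1)x(p-1), beta updated in place.
static void lasso_cd(const NumericMatrix& V, const NumericVector& s,
                     const NumericVector& r, NumericVector& beta,
                     double tol, int max_iter) {
  const int p = s.size();
  for (int it = 0; it < max_iter; ++it) {
    double delta = 0.0;
    for (int k = 0; k < p; ++k) {
      double resid = s[k];
      for (int l = 0; l < p; ++l) resid -= V(k, l) * beta[l];
      resid += V(k, k) * beta[k];
      double bk = 0.0;
      if (resid > r[k]) bk = (resid - r[k]) / V(k, k);
      else if (resid < -r[k]) bk = (resid + r[k]) / V(k, k);
      double d = std::fabs(bk - beta[k]);
      if (d > delta) delta = d;
      beta[k] = bk;
    }
    if (delta < tol) break;
  }
}

// Block coordinate descent graphical lasso with an element-wise penalty
// matrix (Friedman, Hastie & Tibshirani). Returns the working covariance W
// and the regression coefficients B needed to recover the precision matrix.
// [[Rcpp::export(name = ".glasso_cpp")]]
List glasso_cpp(NumericMatrix S, NumericMatrix rho, double tol, int max_iter,
                double cd_tol, int cd_max_iter) {
  const int p = S.nrow();
  NumericMatrix W = clone(S);
  NumericMatrix B(p, p);
  double mean_off = 0.0;
  int n_off = 0;
  for (int i = 0; i < p; ++i)
    for (int j = i + 1; j < p; ++j) { mean_off += std::fabs(S(i, j)); ++n_off; }
  mean_off = (n_off > 0 && mean_off > 0) ? mean_off / n_off : 1.0;

  NumericMatrix V(p - 1, p - 1);
  NumericVector s12(p - 1), r12(p - 1), beta(p - 1);
  bool converged = false;
  int it = 0;
  for (; it < max_iter && !converged; ++it) {
    double delta = 0.0;
    for (int j = 0; j < p; ++j) {
      int a = 0;
      for (int c = 0; c < p; ++c) {
        if (c == j) continue;
        int b = 0;
        for (int r = 0; r < p; ++r) {
          if (r == j) continue;
          V(b, a) = W(r, c);
          ++b;
        }
        s12[a] = S(c, j);
        r12[a] = rho(c, j);
        beta[a] = B(c, j);
        ++a;
      }
      lasso_cd(V, s12, r12, beta, cd_tol, cd_max_iter);
      a = 0;
      for (int c = 0; c < p; ++c) {
        if (c == j) continue;
        B(c, j) = beta[a];
        ++a;
      }
      a = 0;
      for (int r = 0; r < p; ++r) {
        if (r == j) continue;
        double w = 0.0;
        int b = 0;
        for (int c = 0; c < p; ++c) {
          if (c == j) continue;
          w += W(r, c) * beta[b];
          ++b;
        }
        double d = std::fabs(w - W(r, j));
        if (d > delta) delta = d;
        W(r, j) = w;
        W(j, r) = w;
        ++a;
      }
    }
    if (delta / mean_off < tol) converged = true;
  }
  return List::create(_["w"] = W, _["B"] = B, _["iterations"] = it,
                      _["converged"] = converged);
}
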