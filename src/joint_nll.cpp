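#include <Rcpp.h>
using namespace Rcpp;

// Negative marginal log-likelihood of the joint model, integrated over the
// (intercept, slope) random effects by adaptive Gauss-Hermite quadrature on
// per-subject node grids prepared in R.
//
// Per subject i and node q the integrand (on the log scale) is
//   logw_iq                               adaptive weight, incl. 2*det(L_i)
// + delta_i * log h_i(T_i | b_iq)         event contribution
// - Lambda_i(T_i | b_iq)                  cumulative hazard (Gauss-Legendre)
// + sum_j log N(y_ij; m_ij(b_iq), s2)     longitudinal contribution
// + log N2(b_iq; 0, D)                    random-effects density
// and the subject log-likelihood is the log-sum-exp over q.
//
// Fixed-effect parts of the trajectory (X beta) are evaluated in R and
// passed as mfix_* vectors, so this routine is independent of the fixed
// design (linear or spline).
// [[Rcpp::export]]
NumericVector joint_nll_cpp(
    NumericVector y, NumericVector t_long, NumericVector mfix_long,
    IntegerVector subj_long,
    NumericVector Tobs, IntegerVector delta, NumericVector eta_w,
    NumericVector mfix_T,
    NumericVector s_gl, NumericVector base_gl, NumericVector mfix_gl,
    IntegerVector subj_gl,
    NumericMatrix B0, NumericMatrix B1, NumericMatrix logw,
    double sigma, double phi, double alpha,
    double di11, double di12, double di22, double logdetD) {

  const int n = Tobs.size();
  const int Q = B0.ncol();
  const int N = y.size();
  const int M = s_gl.size();

  NumericMatrix acc(n, Q);
  std::vector<int> nobs(n, 0);
  const double log2pi = std::log(2.0 * M_PI);

  // event term, random-effects density, adaptive weights
  for (int i = 0; i < n; ++i) {
    double lhT = std::log(phi) + (phi - 1.0) * std::log(Tobs[i]) + eta_w[i];
    for (int q = 0; q < Q; ++q) {
      double b0 = B0(i, q), b1 = B1(i, q);
      double a = logw(i, q)
        - log2pi - 0.5 * logdetD
        - 0.5 * (di11 * b0 * b0 + 2.0 * di12 * b0 * b1 + di22 * b1 * b1);
      if (delta[i] == 1)
        a += lhT + alpha * (mfix_T[i] + b0 + b1 * Tobs[i]);
      acc(i, q) = a;
    }
  }

  // cumulative hazard by per-subject Gauss-Legendre sums
  {
    std::vector<double> lam(Q);
    int cur = (M > 0) ? subj_gl[0] : -1;
    std::fill(lam.begin(), lam.end(), 0.0);
    for (int r = 0; r < M; ++r) {
      int i = subj_gl[r];
      if (i != cur) {
        double ew = std::exp(eta_w[cur]);
        for (int q = 0; q < Q; ++q) acc(cur, q) -= ew * lam[q];
        std::fill(lam.begin(), lam.end(), 0.0);
        cur = i;
      }
      double s = s_gl[r];
      double am = alpha * mfix_gl[r];
      for (int q = 0; q < Q; ++q)
        lam[q] += base_gl[r] * std::exp(am + alpha * (B0(i, q) + B1(i, q) * s));
    }
    if (cur >= 0) {
      double ew = std::exp(eta_w[cur]);
      for (int q = 0; q < Q; ++q) acc(cur, q) -= ew * lam[q];
    }
  }

  // longitudinal residual sums of squares
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  for (int j = 0; j < N; ++j) {
    int i = subj_long[j];
    ++nobs[i];
    double base = y[j] - mfix_long[j];
    double tj = t_long[j];
    for (int q = 0; q < Q; ++q) {
      double r = base - B0(i, q) - B1(i, q) * tj;
      acc(i, q) -= r * r * inv2s2;
    }
  }
  const double lnorm = 0.5 * std::log(2.0 * M_PI * sigma * sigma);

  NumericVector ll(n);
  for (int i = 0; i < n; ++i) {
    double mx = R_NegInf;
    for (int q = 0; q < Q; ++q) if (acc(i, q) > mx) mx = acc(i, q);
    if (!std::isfinite(mx)) { ll[i] = R_NegInf; continue; }
    double s = 0.0;
    for (int q = 0; q < Q; ++q) s += std::exp(acc(i, q) - mx);
    ll[i] = mx + std::log(s) - nobs[i] * lnorm;
  }
  return ll;
}
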