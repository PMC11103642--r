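#include <Rcpp.h>
using namespace Rcpp;

// Forward (marginalized) CJS log-likelihood, one value per individual.
// y: n x T detection matrix; f: 1-based release occasions;
// phi: n x (T-1), phi(i, t) = survival over interval (t+1, t+2] in 1-based
// occasion numbering (i.e. 0-based: from occasion t to t+1);
// p: n x T detection probabilities (p = 0 encodes structural zeros).
// Probabilities are renormalized every step to avoid underflow.
// [[Rcpp::export]]
NumericVector cpp_cjs_loglik(IntegerMatrix y, IntegerVector f,
                             NumericMatrix phi, NumericMatrix p) {
  int n = y.nrow(), T = y.ncol();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int fi = f[i] - 1;
    double a_alive = 1.0, a_dead = 0.0, ll = 0.0;
    bool impossible = false;
    for (int t = fi; t < T - 1 && !impossible; ++t) {
      double ph = phi(i, t);
      double pr = p(i, t + 1);
      double na, nd;
      if (y(i, t + 1) == 1) {
        na = a_alive * ph * pr;
        nd = 0.0;
      } else {
        na = a_alive * ph * (1.0 - pr);
        nd = a_alive * (1.0 - ph) + a_dead;
      }
      double s = na + nd;
      if (s <= 0.0) {
        impossible = true;
      } else {
        ll += std::log(s);
        a_alive = na / s;
        a_dead = nd / s;
      }
    }
    out[i] = impossible ? R_NegInf : ll;
  }
  return out;
}

// Same forward recursion, but evaluated from linear-predictor pieces so the
// sampler never materializes full probability matrices in R:
//   logit(phi(i,t)) = lp_phi(i,t) + v_phi(t)   [t = interval t -> t+1]
//   logit(p(i,t))   = base_p(t) + eps(i)       [-Inf encodes effort "none"]
// [[Rcpp::export]]
NumericVector cpp_cjs_loglik_pred(IntegerMatrix y, IntegerVector f,
                                  NumericMatrix lp_phi, NumericVector v_phi,
                                  NumericVector base_p, NumericVector eps) {
  int n = y.nrow(), T = y.ncol();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int fi = f[i] - 1;
    double a_alive = 1.0, a_dead = 0.0, ll = 0.0;
    bool impossible = false;
    for (int t = fi; t < T - 1 && !impossible; ++t) {
      double ph = 1.0 / (1.0 + std::exp(-(lp_phi(i, t) + v_phi[t])));
      double bp = base_p[t + 1];
      double pr = (bp == R_NegInf) ? 0.0 :
        1.0 / (1.0 + std::exp(-(bp + eps[i])));
      double na, nd;
      if (y(i, t + 1) == 1) {
        na = a_alive * ph * pr;
        nd = 0.0;
      } else {
        na = a_alive * ph * (1.0 - pr);
        nd = a_alive * (1.0 - ph) + a_dead;
      }
      double s = na + nd;
      if (s <= 0.0) {
        impossible = true;
      } else {
        ll += std::log(s);
        a_alive = na / s;
        a_dead = nd / s;
      }
    }
    out[i] = impossible ? R_NegInf : ll;
  }
  return out;
}

// Observed m-array: rows are release occasions 1..T-1, columns 1..T-1 are
// first-recapture occasions 2..T (column j-1 for recapture at occasion j),
// the last column counts releases never seen again. Every detection before
// the final occasion is a release.
// [[Rcpp::export]]
IntegerMatrix cpp_marray(IntegerMatrix y, IntegerVector f) {
  int n = y.nrow(), T = y.ncol();
  IntegerMatrix m(T - 1, T);
  for (int i = 0; i < n; ++i) {
    int last = -1;
    for (int t = f[i] - 1; t < T; ++t) {
      if (y(i, t) == 1) {
        if (last >= 0) m(last, t - 1)++;
        last = (t < T - 1) ? t : -2;  // detection at final occasion: no release
      }
    }
    if (last >= 0) m(last, T - 1)++;
  }
  return m;
}

// Expected m-array under given phi/p matrices, conditioning on the observed
// releases (cells of y equal to 1 before the final occasion). Cell (t, j):
// survive from t to j undetected in between, detected at j.
// [[Rcpp::export]]
NumericMatrix cpp_expected_marray(IntegerMatrix y, IntegerVector f,
                                  NumericMatrix phi, NumericMatrix p) {
  int n = y.nrow(), T = y.ncol();
  NumericMatrix m(T - 1, T);
  for (int i = 0; i < n; ++i) {
    for (int t = f[i] - 1; t < T - 1; ++t) {
      if (y(i, t) != 1) continue;
      double a = 1.0, total = 0.0;
      for (int j = t + 1; j < T; ++j) {
        a *= phi(i, j - 1);
        double cell = a * p(i, j);
        m(t, j - 1) += cell;
        total += cell;
        a *= (1.0 - p(i, j));
      }
      m(t, T - 1) += 1.0 - total;
    }
  }
  return m;
}
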