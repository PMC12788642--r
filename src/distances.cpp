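#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pairwise Jensen-Shannon divergence (base-2 logs) between the columns of a
// PMF matrix P (n x p, every column sums to one).  Terms with zero mass
// contribute zero by the continuous extension of x log x; coordinates where
// both masses vanish are skipped (the mixture is zero there too).
// [[Rcpp::export]]
NumericMatrix js_divergence_matrix_cpp(NumericMatrix P) {
  const int n = P.nrow(), p = P.ncol();
  NumericMatrix D(p, p);
  const double log2e = 1.0 / std::log(2.0);
  for (int i = 0; i < p; ++i) {
    for (int j = i + 1; j < p; ++j) {
      double acc = 0.0;
      for (int k = 0; k < n; ++k) {
        const double a = P(k, i), b = P(k, j);
        const double m = 0.5 * (a + b);
        if (m <= 0.0) continue;
        if (a > 0.0) acc += 0.5 * a * std::log(a / m) * log2e;
        if (b > 0.0) acc += 0.5 * b * std::log(b / m) * log2e;
      }
      if (acc < 0.0) acc = 0.0;  // guard against rounding just below zero
      D(i, j) = acc;
      D(j, i) = acc;
    }
  }
  return D;
}

// Pairwise tropical (max-plus) distance between columns of X:
// d(i, j) = max_k (x_ki - x_kj) - min_k (x_ki - x_kj).
// [[Rcpp::export]]
NumericMatrix tropical_distance_matrix_cpp(NumericMatrix X) {
  const int n = X.nrow(), p = X.ncol();
  NumericMatrix D(p, p);
  for (int i = 0; i < p; ++i) {
    for (int j = i + 1; j < p; ++j) {
      double mx = R_NegInf, mn = R_PosInf;
      for (int k = 0; k < n; ++k) {
        const double d = X(k, i) - X(k, j);
        if (d > mx) mx = d;
        if (d < mn) mn = d;
      }
      D(i, j) = mx - mn;
      D(j, i) = mx - mn;
    }
  }
  return D;
}
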