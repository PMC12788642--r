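#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// err(R', Q) over the lower triangle where R'[i,j] = R[perm[i], perm[j]].
static double layout_error(const int* R, const int* Q, const std::vector<int>& perm,
                           int p) {
  double err = 0.0;
  for (int i = 1; i < p; ++i) {
    const int pi = perm[i];
    for (int j = 0; j < i; ++j) {
      const double d = (double)R[pi + p * perm[j]] - (double)Q[i + p * j];
      err += d * d;
    }
  }
  return err;
}

// Change in err(R', Q) caused by swapping the features at grid positions a
// and b.  Only pairs touching a or b change; the (a, b) pair itself is
// unaffected because both R and Q are symmetric.  O(p).
static double swap_delta(const int* R, const int* Q, const std::vector<int>& perm,
                         int p, int a, int b) {
  const int pa = perm[a], pb = perm[b];
  double delta = 0.0;
  for (int j = 0; j < p; ++j) {
    if (j == a || j == b) continue;
    const int pj = perm[j];
    const double ra = (double)R[pa + p * pj];
    const double rb = (double)R[pb + p * pj];
    const double qa = (double)Q[a + p * j];
    const double qb = (double)Q[b + p * j];
    delta += (rb - qa) * (rb - qa) + (ra - qb) * (ra - qb)
           - (ra - qa) * (ra - qa) - (rb - qb) * (rb - qb);
  }
  return delta;
}

// [[Rcpp::export]]
double igtd_swap_delta_cpp(IntegerMatrix R, IntegerMatrix Q, IntegerVector perm1,
                           int a1, int b1) {
  const int p = R.nrow();
  std::vector<int> perm(p);
  for (int i = 0; i < p; ++i) perm[i] = perm1[i] - 1;
  return swap_delta(R.begin(), Q.begin(), perm, p, a1 - 1, b1 - 1);
}

// [[Rcpp::export]]
double igtd_error_perm_cpp(IntegerMatrix R, IntegerMatrix Q, IntegerVector perm1) {
  const int p = R.nrow();
  std::vector<int> perm(p);
  for (int i = 0; i < p; ++i) perm[i] = perm1[i] - 1;
  return layout_error(R.begin(), Q.begin(), perm, p);
}

// Greedy swap optimisation of the feature-to-pixel assignment.
// At each iteration the grid position with the largest error contribution
// (among positions not selected within the last `cooldown` iterations) is
// chosen; swapping it against every other position is evaluated with the
// O(p) incremental update, and the best strictly improving swap is applied
// (ties broken by the smallest partner index).  Terminates after `max_steps`
// iterations or `stall_limit` consecutive iterations without improvement.
// [[Rcpp::export]]
List igtd_optimize_cpp(IntegerMatrix Rm, IntegerMatrix Qm, int max_steps,
                       int stall_limit, int cooldown) {
  const int p = Rm.nrow();
  const int* R = Rm.begin();
  const int* Q = Qm.begin();
  std::vector<int> perm(p);
  for (int i = 0; i < p; ++i) perm[i] = i;

  double err = layout_error(R, Q, perm, p);
  std::vector<double> trace;
  trace.push_back(err);
  std::vector<int> last_sel(p, -cooldown - 1);
  std::vector<double> contrib(p);
  int stall = 0;

  for (int it = 0; it < max_steps && err > 0.0; ++it) {
    if (stall >= stall_limit) break;
    // per-position error contributions under the current permutation
    for (int i = 0; i < p; ++i) contrib[i] = 0.0;
    for (int i = 1; i < p; ++i) {
      const int pi = perm[i];
      for (int j = 0; j < i; ++j) {
        const double d = (double)R[pi + p * perm[j]] - (double)Q[i + p * j];
        const double d2 = d * d;
        contrib[i] += d2;
        contrib[j] += d2;
      }
    }
    // pick the worst position among those off cooldown (fall back to the
    // overall worst when every position is cooling down)
    int a = -1;
    double best_c = -1.0;
    for (int i = 0; i < p; ++i) {
      if (it - last_sel[i] <= cooldown) continue;
      if (contrib[i] > best_c) { best_c = contrib[i]; a = i; }
    }
    if (a < 0) {
      for (int i = 0; i < p; ++i)
        if (contrib[i] > best_c) { best_c = contrib[i]; a = i; }
    }
    last_sel[a] = it;

    int best_b = -1;
    double best_delta = 0.0;
    for (int b = 0; b < p; ++b) {
      if (b == a) continue;
      const double d = swap_delta(R, Q, perm, p, a, b);
      if (d < best_delta - 1e-9) { best_delta = d; best_b = b; }
    }
    if (best_b >= 0) {
      std::swap(perm[a], perm[best_b]);
      err += best_delta;
      if (err < 0.0) err = 0.0;
      trace.push_back(err);
      stall = 0;
    } else {
      ++stall;
    }
  }

  IntegerVector perm_out(p);
  for (int i = 0; i < p; ++i) perm_out[i] = perm[i] + 1;
  return List::create(_["perm"] = perm_out,
                      _["error"] = err,
                      _["error_trace"] = NumericVector(trace.begin(), trace.end()));
}
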