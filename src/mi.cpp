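#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Plug-in mutual information in bits between two discrete vectors coded
// 0..nx-1 and 0..ny-1; 0 * log 0 = 0.
static double mi_pair(const int* x, const int* y, int n, int nx, int ny) {
  std::vector<double> joint((size_t)nx * ny, 0.0);
  std::vector<double> px(nx, 0.0), py(ny, 0.0);
  for (int i = 0; i < n; ++i) {
    joint[(size_t)x[i] * ny + y[i]] += 1.0;
    px[x[i]] += 1.0;
    py[y[i]] += 1.0;
  }
  double mi = 0.0, dn = (double)n;
  for (int a = 0; a < nx; ++a) {
    if (px[a] == 0.0) continue;
    for (int b = 0; b < ny; ++b) {
      double j = joint[(size_t)a * ny + b];
      if (j > 0.0)
        mi += (j / dn) * std::log2(j * dn / (px[a] * py[b]));
    }
  }
  return mi < 0.0 ? 0.0 : mi;
}

// [[Rcpp::export(name = ".mi_pair_cpp")]]
double mi_pair_cpp(IntegerVector x, IntegerVector y, int nx, int ny) {
  return mi_pair(INTEGER(x), INTEGER(y), x.size(), nx, ny);
}

// MI of every column of X (codes 0..nbin-1) with y (codes 0..ny-1).
// [[Rcpp::export(name = ".mi_columns_cpp")]]
NumericVector mi_columns_cpp(IntegerMatrix X, IntegerVector y, int nbin, int ny) {
  int n = X.nrow(), p = X.ncol();
  NumericVector out(p);
  const int* yp = INTEGER(y);
  for (int j = 0; j < p; ++j)
    out[j] = mi_pair(&X(0, j), yp, n, nbin, ny);
  return out;
}

// Greedy first-order incremental mRMR on a discretized matrix.
// Step 1 picks argmax I(x_j; c); each later step picks
// argmax I(x_j; c) - (1/|S|) sum_{x_i in S} I(x_j; x_i).
// Criterion ties break toward lower accumulated redundancy (the
// minimal-redundancy spirit: an uninformative but novel feature beats an
// exact copy), then toward the lowest column index. Returns 1-based order
// and the criterion value at each step.
// [[Rcpp::export(name = ".mrmr_rank_cpp")]]
List mrmr_rank_cpp(IntegerMatrix X, IntegerVector y, int m, int nbin, int ny) {
  int n = X.nrow(), p = X.ncol();
  const int* yp = INTEGER(y);
  std::vector<double> relev(p);
  for (int j = 0; j < p; ++j) relev[j] = mi_pair(&X(0, j), yp, n, nbin, ny);

  std::vector<bool> used(p, false);
  std::vector<double> redsum(p, 0.0);  // sum of MI with already-selected
  IntegerVector order(m);
  NumericVector crit(m);

  const double eps = 1e-12;
  for (int step = 0; step < m; ++step) {
    int best = -1;
    double bestval = 0.0;
    for (int j = 0; j < p; ++j) {
      if (used[j]) continue;
      double val = (step == 0) ? relev[j] : relev[j] - redsum[j] / step;
      bool take = best < 0 || val > bestval + eps;
      if (!take && best >= 0 && val > bestval - eps)
        take = redsum[j] < redsum[best] - eps;  // tie: less redundant wins
      if (take) {
        best = j;
        bestval = val;
      }
    }
    order[step] = best + 1;
    crit[step] = bestval;
    used[best] = true;
    if (step + 1 < m) {
      for (int j = 0; j < p; ++j) {
        if (used[j]) continue;
        redsum[j] += mi_pair(&X(0, j), &X(0, best), n, nbin, nbin);
      }
    }
  }
  return List::create(_["order"] = order, _["criterion"] = crit,
                      _["relevance"] = NumericVector(relev.begin(), relev.end()));
}
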