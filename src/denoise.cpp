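#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Daubechies scaling filter with 4 vanishing moments (8 taps), L2-normalised.
static const int NTAP = 8;
static const double H[NTAP] = {
    0.23037781330885523,  0.71484657055254153,  0.63088076792959036,
   -0.02798376941698385, -0.18703481171888114,  0.03084138183598697,
    0.03288301166698295, -0.01059740178499728};

// One periodic analysis level: x (length n, n even) -> approx a, detail d (n/2).
static void dwt_level(const std::vector<double>& x, int n,
                      std::vector<double>& a, std::vector<double>& d) {
  int h = n / 2;
  for (int i = 0; i < h; ++i) {
    double sa = 0.0, sd = 0.0;
    for (int k = 0; k < NTAP; ++k) {
      double v = x[(2 * i + k) % n];
      sa += H[k] * v;
      // quadrature mirror: g[k] = (-1)^k h[NTAP-1-k]
      double g = (k % 2 == 0) ? H[NTAP - 1 - k] : -H[NTAP - 1 - k];
      sd += g * v;
    }
    a[i] = sa;
    d[i] = sd;
  }
}

// Periodic synthesis (adjoint of the orthonormal analysis step).
static void idwt_level(const std::vector<double>& a, const std::vector<double>& d,
                       int n, std::vector<double>& x) {
  std::fill(x.begin(), x.begin() + n, 0.0);
  int h = n / 2;
  for (int i = 0; i < h; ++i) {
    for (int k = 0; k < NTAP; ++k) {
      double g = (k % 2 == 0) ? H[NTAP - 1 - k] : -H[NTAP - 1 - k];
      x[(2 * i + k) % n] += H[k] * a[i] + g * d[i];
    }
  }
}

struct Decomp {
  std::vector<std::vector<double> > details;
  std::vector<double> approx;
};

static void decompose(const std::vector<double>& x, int levels, Decomp& out) {
  std::vector<double> cur = x;
  out.details.clear();
  for (int lev = 0; lev < levels; ++lev) {
    int n = (int)cur.size();
    if (n < 2 || n % 2 != 0) break;
    std::vector<double> a(n / 2), d(n / 2);
    dwt_level(cur, n, a, d);
    out.details.push_back(d);
    cur.swap(a);
  }
  out.approx = cur;
}

static std::vector<double> reconstruct(const Decomp& dec) {
  std::vector<double> cur = dec.approx;
  for (int lev = (int)dec.details.size() - 1; lev >= 0; --lev) {
    int n = 2 * (int)dec.details[lev].size();
    std::vector<double> x(n);
    idwt_level(cur, dec.details[lev], n, x);
    cur.swap(x);
  }
  return cur;
}

static double soft(double v, double t) {
  if (v > t) return v - t;
  if (v < -t) return v + t;
  return 0.0;
}

// Translation-invariant wavelet shrinkage of one channel.
// Cycle spinning over nshift = 2^levels circular shifts covers every decimation
// phase of the multirate filter bank, so with periodic boundaries the operator
// is exactly circular-shift covariant. The noise scale is the MAD of the
// finest-level detail coefficients pooled over all shifts (a shift-invariant
// multiset), and the threshold is universal: sigma * sqrt(2 log n).
static void ti_denoise_channel(const std::vector<double>& x, int levels,
                               std::vector<double>& out) {
  int n = (int)x.size();
  int nshift = 1 << levels;
  if (n < 2 * nshift) { out = x; return; }

  std::vector<Decomp> decs(nshift);
  std::vector<double> shifted(n);
  std::vector<double> fine;
  fine.reserve((size_t)nshift * (n / 2));
  for (int s = 0; s < nshift; ++s) {
    for (int i = 0; i < n; ++i) shifted[i] = x[(i + s) % n];
    decompose(shifted, levels, decs[s]);
    const std::vector<double>& d1 = decs[s].details[0];
    for (size_t i = 0; i < d1.size(); ++i) fine.push_back(std::fabs(d1[i]));
  }
  std::sort(fine.begin(), fine.end());
  size_t m = fine.size();
  double med = (m % 2 == 1) ? fine[m / 2] : 0.5 * (fine[m / 2 - 1] + fine[m / 2]);
  double sigma = med / 0.6744897501960817;  // MAD -> SD for a Gaussian
  double thr = sigma * std::sqrt(2.0 * std::log((double)n));

  std::fill(out.begin(), out.end(), 0.0);
  for (int s = 0; s < nshift; ++s) {
    for (size_t lev = 0; lev < decs[s].details.size(); ++lev) {
      std::vector<double>& d = decs[s].details[lev];
      for (size_t i = 0; i < d.size(); ++i) d[i] = soft(d[i], thr);
    }
    std::vector<double> rec = reconstruct(decs[s]);
    for (int i = 0; i < n; ++i) out[(i + s) % n] += rec[i];
  }
  double inv = 1.0 / nshift;
  for (int i = 0; i < n; ++i) out[i] *= inv;
}

// [[Rcpp::export(name = ".ti_denoise_cpp")]]
NumericMatrix ti_denoise_cpp(NumericMatrix x, int levels) {
  int n = x.nrow(), p = x.ncol();
  NumericMatrix out(n, p);
  std::vector<double> col(n), den(n);
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) col[i] = x(i, j);
    ti_denoise_channel(col, levels, den);
    for (int i = 0; i < n; ++i) out(i, j) = den[i];
  }
  return out;
}
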