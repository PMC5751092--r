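#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const double EPS = 1e-12;

// Shannon entropy (bits) of a 10-bin equal-width histogram over the epoch's
// own range; 0 for constant epochs (no spread, no detail to encode).
static double entropy_bits(const double* x, int n, double mn, double mx) {
  if (mx - mn <= 0.0) return 0.0;
  const int B = 10;
  int cnt[B];
  for (int b = 0; b < B; ++b) cnt[b] = 0;
  double w = (mx - mn) / B;
  for (int i = 0; i < n; ++i) {
    int b = (int)((x[i] - mn) / w);
    if (b >= B) b = B - 1;
    if (b < 0) b = 0;
    cnt[b]++;
  }
  double hh = 0.0;
  for (int b = 0; b < B; ++b) {
    if (cnt[b] > 0) {
      double p = (double)cnt[b] / n;
      hh -= p * std::log2(p);
    }
  }
  return hh;
}

// Higuchi fractal dimension, k_max = 8. Constant epochs -> 1 (a smooth line).
static double higuchi_fd(const double* x, int n, int kmax) {
  std::vector<double> lk, lnk;
  for (int k = 1; k <= kmax; ++k) {
    double Lk = 0.0;
    int nm = 0;
    for (int m = 0; m < k; ++m) {
      int steps = (n - 1 - m) / k;
      if (steps < 1) continue;
      double Lm = 0.0;
      for (int i = 1; i <= steps; ++i)
        Lm += std::fabs(x[m + i * k] - x[m + (i - 1) * k]);
      Lm *= (double)(n - 1) / ((double)steps * k);
      Lk += Lm / k;
      nm++;
    }
    if (nm == 0) continue;
    Lk /= nm;
    if (Lk > 0.0) {
      lk.push_back(std::log(Lk));
      lnk.push_back(std::log(1.0 / k));
    }
  }
  int m = (int)lk.size();
  if (m < 2) return 1.0;
  double sx = 0, sy = 0, sxx = 0, sxy = 0;
  for (int i = 0; i < m; ++i) {
    sx += lnk[i]; sy += lk[i]; sxx += lnk[i] * lnk[i]; sxy += lnk[i] * lk[i];
  }
  double den = m * sxx - sx * sx;
  if (std::fabs(den) < EPS) return 1.0;
  return (m * sxy - sx * sy) / den;
}

// The 11 per-channel epoch features, in fixed order:
// sd, entropy, cv, mean, max, min, median, slope (per second),
// max/RMS, RMS/mean, Higuchi fractal dimension.
static void channel_features(const double* x, int n, double sample_rate,
                             double* out) {
  double s = 0.0, s2 = 0.0, mx = x[0], mn = x[0];
  for (int i = 0; i < n; ++i) {
    s += x[i];
    s2 += x[i] * x[i];
    if (x[i] > mx) mx = x[i];
    if (x[i] < mn) mn = x[i];
  }
  double mean = s / n;
  double var = (n > 1) ? (s2 - n * mean * mean) / (n - 1) : 0.0;
  if (var < 0.0) var = 0.0;
  double sd = std::sqrt(var);
  double rms = std::sqrt(s2 / n);

  std::vector<double> srt(x, x + n);
  std::sort(srt.begin(), srt.end());
  double med = (n % 2 == 1) ? srt[n / 2] : 0.5 * (srt[n / 2 - 1] + srt[n / 2]);

  // OLS slope against the sample index, reported per second
  double ti = (n - 1) / 2.0, stt = 0.0, sty = 0.0;
  for (int i = 0; i < n; ++i) {
    double dt = i - ti;
    stt += dt * dt;
    sty += dt * (x[i] - mean);
  }
  double slope = (stt > 0.0) ? (sty / stt) * sample_rate : 0.0;

  double dmean = (std::fabs(mean) < EPS) ? EPS : mean;
  double drms = (std::fabs(rms) < EPS) ? EPS : rms;

  out[0] = sd;
  out[1] = entropy_bits(x, n, mn, mx);
  out[2] = sd / dmean;
  out[3] = mean;
  out[4] = mx;
  out[5] = mn;
  out[6] = med;
  out[7] = slope;
  out[8] = mx / drms;
  out[9] = rms / dmean;
  out[10] = higuchi_fd(x, n, 8);
}

// signal: T x C matrix (samples x channels). Returns floor(T/epoch_len) x (11*C),
// channel-major column blocks (channel 1 features 1..11, channel 2 ..., ...).
// [[Rcpp::export(name = ".epoch_features_cpp")]]
NumericMatrix epoch_features_cpp(NumericMatrix signal, int epoch_len,
                                 double sample_rate) {
  int T = signal.nrow(), C = signal.ncol();
  int ne = T / epoch_len;
  NumericMatrix out(ne, 11 * C);
  std::vector<double> buf(epoch_len);
  double f[11];
  for (int c = 0; c < C; ++c) {
    for (int e = 0; e < ne; ++e) {
      int off = e * epoch_len;
      for (int i = 0; i < epoch_len; ++i) buf[i] = signal(off + i, c);
      channel_features(buf.data(), epoch_len, sample_rate, f);
      for (int j = 0; j < 11; ++j) out(e, 11 * c + j) = f[j];
    }
  }
  return out;
}
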