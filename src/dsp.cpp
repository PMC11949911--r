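#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Direct-form-II-transposed IIR filter, one channel. a[0] must be 1.
// [[Rcpp::export(name = ".iirFilter")]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x) {
  int nb = b.size(), na = a.size(), n = x.size();
  int m = std::max(nb, na);
  std::vector<double> z(m, 0.0);
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xn = x[i];
    double yn = b[0] * xn + z[0];
    for (int k = 1; k < m; ++k) {
      double bk = (k < nb) ? b[k] : 0.0;
      double ak = (k < na) ? a[k] : 0.0;
      z[k - 1] = bk * xn - ak * yn + ((k < m - 1) ? z[k] : 0.0);
    }
    y[i] = yn;
  }
  return y;
}

// Feedback comb filter: y[n] = x[n - d] + g * y[n - d]
static std::vector<double> comb(const NumericVector& x, int d, double g) {
  int n = x.size();
  std::vector<double> y(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double xd = (i >= d) ? x[i - d] : 0.0;
    double yd = (i >= d) ? y[i - d] : 0.0;
    y[i] = xd + g * yd;
  }
  return y;
}

// Schroeder allpass: y[n] = -g x[n] + x[n - d] + g y[n - d]
static void allpass_inplace(std::vector<double>& x, int d, double g) {
  int n = x.size();
  std::vector<double> y(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double xd = (i >= d) ? x[i - d] : 0.0;
    double yd = (i >= d) ? y[i - d] : 0.0;
    y[i] = -g * x[i] + xd + g * yd;
  }
  x.swap(y);
}

// Schroeder reverberator (4 parallel combs + 2 series allpasses), returning
// the wet signal only; the caller applies the dry/wet mix.
// [[Rcpp::export(name = ".schroederWet")]]
NumericVector schroeder_wet(NumericVector x, double fs) {
  const double combDelaysMs[4] = {29.7, 37.1, 41.1, 43.7};
  const double combGains[4] = {0.805, 0.827, 0.783, 0.764};
  const double apDelaysMs[2] = {5.0, 1.7};
  const double apGain = 0.7;
  int n = x.size();
  std::vector<double> acc(n, 0.0);
  for (int c = 0; c < 4; ++c) {
    int d = std::max(1, (int)std::lround(combDelaysMs[c] * fs / 1000.0));
    std::vector<double> y = comb(x, d, combGains[c]);
    for (int i = 0; i < n; ++i) acc[i] += 0.25 * y[i];
  }
  for (int a = 0; a < 2; ++a) {
    int d = std::max(1, (int)std::lround(apDelaysMs[a] * fs / 1000.0));
    allpass_inplace(acc, d, apGain);
  }
  return NumericVector(acc.begin(), acc.end());
}

// Flanger: dry/wet mix of the input with a copy delayed by
// base + depth * sin(2 pi f t), linear interpolation in the delay line.
// [[Rcpp::export(name = ".flangerChannel")]]
NumericVector flanger_channel(NumericVector x, double fs, double power,
                              double freq, double baseDelayMs,
                              double depthMs) {
  int n = x.size();
  NumericVector y(n);
  double base = baseDelayMs * fs / 1000.0;
  double depth = depthMs * fs / 1000.0;
  double w = 2.0 * M_PI * freq / fs;
  for (int i = 0; i < n; ++i) {
    double d = base + depth * std::sin(w * i);
    double pos = i - d;
    double wet = 0.0;
    if (pos >= 0) {
      int i0 = (int)std::floor(pos);
      double frac = pos - i0;
      double x0 = x[i0];
      double x1 = (i0 + 1 < n) ? x[i0 + 1] : x0;
      wet = (1.0 - frac) * x0 + frac * x1;
    }
    y[i] = (1.0 - power) * x[i] + power * wet;
  }
  return y;
}

// Change suppression: frame the signal into consecutive blocks of
// frameLength samples; per frame compute its amplitude (mean absolute value,
// or RMS when useRms); once 17 frames have been seen, average the last 16
// frame-to-frame amplitude differences. When that average exceeds the
// threshold the gain drops immediately to `suppression` and then relaxes
// linearly back to 1 over backTime seconds; re-triggering restarts the ramp.
// Detection runs on the channel mean; the same gain is applied per sample to
// every channel. Returns the processed matrix and the per-sample gain.
// [[Rcpp::export(name = ".changeSuppression")]]
List change_suppression(NumericMatrix x, double fs, double threshold,
                        double suppression, double backTime,
                        int frameLength, bool useRms) {
  int n = x.nrow(), nc = x.ncol();
  int nFrames = n / frameLength;
  NumericMatrix out(n, nc);
  NumericVector gain(n);
  // amplitude of the mono mix per frame
  std::vector<double> amp(nFrames, 0.0);
  for (int f = 0; f < nFrames; ++f) {
    double acc = 0.0;
    for (int i = f * frameLength; i < (f + 1) * frameLength; ++i) {
      double m = 0.0;
      for (int c = 0; c < nc; ++c) m += x(i, c);
      m /= nc;
      acc += useRms ? m * m : std::fabs(m);
    }
    acc /= frameLength;
    amp[f] = useRms ? std::sqrt(acc) : acc;
  }
  double g = 1.0;
  double slope = (backTime > 0) ? (1.0 - suppression) / (backTime * fs) : 0.0;
  int idx = 0;
  for (int f = 0; f < nFrames; ++f) {
    if (f >= 16) {
      double meanDiff = (amp[f] - amp[f - 16]) / 16.0;
      if (meanDiff > threshold) g = suppression;  // (re)trigger
    }
    for (int i = 0; i < frameLength; ++i, ++idx) {
      gain[idx] = g;
      for (int c = 0; c < nc; ++c) out(idx, c) = x(idx, c) * g;
      if (g < 1.0) {
        g += slope;
        if (g > 1.0) g = 1.0;
      }
    }
  }
  for (; idx < n; ++idx) {  // tail shorter than one frame
    gain[idx] = g;
    for (int c = 0; c < nc; ++c) out(idx, c) = x(idx, c) * g;
  }
  return List::create(_["samples"] = out, _["gain"] = gain);
}
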