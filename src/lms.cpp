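#include <Rcpp.h>
#include <cmath>
#include <vector>

// Adaptive transversal power-line canceller for one channel (offline,
// two-pass). Reference inputs are unit-amplitude sine/cosine pairs at
// k*line_freq, k = 1..n_harmonics; weights follow the LMS rule
// w += 2*mu*e*r. Pass 1 adapts over the whole signal with the
// stochastic-approximation schedule mu(t) = mu0*T0/(T0+t), T0 = tau_s*fs,
// driving both bias and gradient-noise jitter down; pass 2 re-processes
// the signal from the converged weights with the small tracking step
// mu_ss and emits the residual (input minus estimated interference).
// [[Rcpp::export(name = "lms_cancel")]]
Rcpp::NumericVector lms_cancel(Rcpp::NumericVector x, double fs,
                               double line_freq, int n_harmonics,
                               double mu_ss, double mu0, double tau_s) {
  const int n = x.size();
  const int k = n_harmonics;
  Rcpp::NumericVector out(n);
  std::vector<double> w(2 * k, 0.0), ref(2 * k);
  std::vector<double> omega(k);
  for (int h = 0; h < k; ++h)
    omega[h] = 2.0 * M_PI * line_freq * (h + 1) / fs;
  const double T0 = tau_s * fs;

  for (int pass = 0; pass < 2; ++pass) {
    const bool adapt_pass = (pass == 0);
    for (int t = 0; t < n; ++t) {
      double est = 0.0;
      for (int h = 0; h < k; ++h) {
        ref[2 * h]     = std::sin(omega[h] * t);
        ref[2 * h + 1] = std::cos(omega[h] * t);
        est += w[2 * h] * ref[2 * h] + w[2 * h + 1] * ref[2 * h + 1];
      }
      const double e = x[t] - est;
      const double mu = adapt_pass ? mu0 * T0 / (T0 + t) : mu_ss;
      for (int j = 0; j < 2 * k; ++j)
        w[j] += 2.0 * mu * e * ref[j];
      if (!adapt_pass) out[t] = e;
    }
  }
  return out;
}
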