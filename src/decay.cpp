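#include <Rcpp.h>
using namespace Rcpp;

// Sum of exponentials on a uniform time grid:
//   out[j] = sum_k amp[k] * exp(-(t0 + j*dt) * rate[k]),  j = 0..n-1
// Evaluated with a per-component geometric recurrence (one exp per component
// instead of one per bin), which is the hot path of the distance-averaged
// FRET decay where k runs over (lifetime component) x (distance grid point).
// [[Rcpp::export]]
NumericVector expsum_grid(double t0, double dt, int n,
                          NumericVector amp, NumericVector rate) {
  if (amp.size() != rate.size())
    stop("amp and rate must have equal length");
  NumericVector out(n);
  const int K = amp.size();
  for (int k = 0; k < K; ++k) {
    const double a = amp[k];
    if (a == 0.0) continue;
    const double r = rate[k];
    double v = a * std::exp(-t0 * r);
    const double d = std::exp(-dt * r);
    for (int j = 0; j < n; ++j) {
      out[j] += v;
      v *= d;
    }
  }
  return out;
}
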