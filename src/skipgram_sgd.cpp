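#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double sigmoid(double x) {
  return 1.0 / (1.0 + std::exp(-x));
}

// xorshift128+ generator: negative sampling needs millions of draws per
// epoch and calling back into R's RNG dominates the runtime; an explicit
// seed keeps the run deterministic.
static inline double xs_next(uint64_t s[2]) {
  uint64_t x = s[0];
  const uint64_t y = s[1];
  s[0] = y;
  x ^= x << 23;
  s[1] = x ^ y ^ (x >> 17) ^ (y >> 26);
  return (double)((s[1] + y) >> 11) / 9007199254740992.0;  // [0,1)
}

// One pass of skip-gram SGD with negative sampling over precomputed
// (center, context) pairs. vin_t / vout_t are T x W matrices (transposed
// storage, so one word's vector is a contiguous column) updated in place.
// neg_cdf is the cumulative unigram^0.75 sampling distribution over words.
// lr decays linearly from lr_start to lr_min across total_updates,
// starting at update counter `done` (so decay spans all epochs).
// [[Rcpp::export]]
double sgns_epoch(NumericMatrix vin_t, NumericMatrix vout_t,
                  const IntegerVector& center, const IntegerVector& context,
                  const NumericVector& neg_cdf,
                  int n_negative, double lr_start, double lr_min,
                  double total_updates, double done, int seed) {
  const int T = vin_t.nrow();
  const int W = vin_t.ncol();
  const int P = center.size();
  std::vector<double> grad_in(T);
  double obj = 0.0;
  double* vin = REAL(vin_t);
  double* vout = REAL(vout_t);
  uint64_t rs[2] = { 0x9E3779B97F4A7C15ULL ^ (uint64_t)seed,
                     0xBF58476D1CE4E5B9ULL + (uint64_t)seed };
  for (int i = 0; i < 16; ++i) xs_next(rs);  // warm up

  for (int p = 0; p < P; ++p) {
    double lr = lr_start * (1.0 - (done + p) / total_updates);
    if (lr < lr_min) lr = lr_min;
    const int wi = center[p], wo = context[p];
    double* vi = vin + (size_t)wi * T;
    std::fill(grad_in.begin(), grad_in.end(), 0.0);

    for (int s = 0; s <= n_negative; ++s) {
      int target;
      double lab;
      if (s == 0) { target = wo; lab = 1.0; }
      else {
        const double u = xs_next(rs);
        target = (int)(std::lower_bound(neg_cdf.begin(), neg_cdf.end(), u)
                       - neg_cdf.begin());
        if (target >= W) target = W - 1;
        if (target == wo) continue;
        lab = 0.0;
      }
      double* vo = vout + (size_t)target * T;
      double dot = 0.0;
      for (int t = 0; t < T; ++t) dot += vi[t] * vo[t];
      const double pred = sigmoid(dot);
      obj += lab > 0.5 ? std::log(pred + 1e-12) : std::log(1.0 - pred + 1e-12);
      const double g = lr * (lab - pred);
      for (int t = 0; t < T; ++t) {
        grad_in[t] += g * vo[t];
        vo[t] += g * vi[t];
      }
    }
    for (int t = 0; t < T; ++t) vi[t] += grad_in[t];
  }
  return obj / P;
}
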