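#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sweeps for latent Dirichlet allocation.
// tokens, doc: 0-based flat token/word ids and their document ids.
// z: 0-based initial topic assignments.
// avg_last: if > 0, the smoothed document-topic distribution
// (C_dk + alpha) / (len_d + K alpha) is accumulated after each of the last
// avg_last sweeps (posterior-mean features); theta_sum is returned
// unnormalized (divide by avg_last).
// Uses R's RNG so runs are reproducible under set.seed().
// [[Rcpp::export]]
List gibbs_lda_sweeps(const IntegerVector& tokens,
                      const IntegerVector& doc,
                      const IntegerVector& z,
                      int K, int W, int D,
                      double alpha, double beta,
                      int n_iter, int avg_last = 0) {
  const int N = tokens.size();
  std::vector<int> cdk((size_t)D * K, 0);
  std::vector<int> cwk((size_t)W * K, 0);
  std::vector<int> ck(K, 0);
  std::vector<int> dlen(D, 0);
  IntegerVector zz = clone(z);
  NumericMatrix theta_sum(D, K);

  for (int n = 0; n < N; ++n) {
    int k = zz[n];
    cdk[(size_t)doc[n] * K + k]++;
    cwk[(size_t)tokens[n] * K + k]++;
    ck[k]++;
    dlen[doc[n]]++;
  }

  std::vector<double> p(K);
  const double wbeta = W * beta;
  for (int it = 0; it < n_iter; ++it) {
    for (int n = 0; n < N; ++n) {
      const int d = doc[n], w = tokens[n];
      int k = zz[n];
      cdk[(size_t)d * K + k]--;
      cwk[(size_t)w * K + k]--;
      ck[k]--;

      double tot = 0.0;
      for (int t = 0; t < K; ++t) {
        tot += (cdk[(size_t)d * K + t] + alpha) *
               (cwk[(size_t)w * K + t] + beta) / (ck[t] + wbeta);
        p[t] = tot;
      }
      const double u = unif_rand() * tot;
      k = 0;
      while (k < K - 1 && p[k] < u) ++k;

      zz[n] = k;
      cdk[(size_t)d * K + k]++;
      cwk[(size_t)w * K + k]++;
      ck[k]++;
    }
    if (avg_last > 0 && it >= n_iter - avg_last) {
      for (int d = 0; d < D; ++d) {
        const double denom = dlen[d] + K * alpha;
        for (int t = 0; t < K; ++t)
          theta_sum(d, t) += (cdk[(size_t)d * K + t] + alpha) / denom;
      }
    }
  }
  return List::create(_["z"] = zz, _["theta_sum"] = theta_sum);
}

// Fold-in sweeps for held-out documents: word-topic counts of the fitted
// model are held fixed; only the new documents' doc-topic counts move.
// [[Rcpp::export]]
List gibbs_lda_foldin(const IntegerVector& tokens,
                      const IntegerVector& doc,
                      const IntegerVector& z,
                      const IntegerMatrix& cwk_fit, // W x K
                      const IntegerVector& ck_fit,  // K
                      int K, int W, int D,
                      double alpha, double beta,
                      int n_iter, int avg_last = 0) {
  const int N = tokens.size();
  std::vector<int> cdk((size_t)D * K, 0);
  std::vector<int> dlen(D, 0);
  IntegerVector zz = clone(z);
  NumericMatrix theta_sum(D, K);
  for (int n = 0; n < N; ++n) {
    cdk[(size_t)doc[n] * K + zz[n]]++;
    dlen[doc[n]]++;
  }

  std::vector<double> p(K);
  const double wbeta = W * beta;
  for (int it = 0; it < n_iter; ++it) {
    for (int n = 0; n < N; ++n) {
      const int d = doc[n], w = tokens[n];
      int k = zz[n];
      cdk[(size_t)d * K + k]--;
      double tot = 0.0;
      for (int t = 0; t < K; ++t) {
        tot += (cdk[(size_t)d * K + t] + alpha) *
               (cwk_fit(w, t) + beta) / (ck_fit[t] + wbeta);
        p[t] = tot;
      }
      const double u = unif_rand() * tot;
      k = 0;
      while (k < K - 1 && p[k] < u) ++k;
      zz[n] = k;
      cdk[(size_t)d * K + k]++;
    }
    if (avg_last > 0 && it >= n_iter - avg_last) {
      for (int d = 0; d < D; ++d) {
        const double denom = dlen[d] + K * alpha;
        for (int t = 0; t < K; ++t)
          theta_sum(d, t) += (cdk[(size_t)d * K + t] + alpha) / denom;
      }
    }
  }
  return List::create(_["z"] = zz, _["theta_sum"] = theta_sum);
}
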