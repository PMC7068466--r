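#include <Rcpp.h>
#include "rng.h"

using namespace Rcpp;

// Collapsed Gibbs sampler for latent Dirichlet allocation.
// docs: list of integer vectors with 0-based vocabulary ids.
// Returns topic-word distribution phi (K x V), document-topic theta (D x K)
// and the global topic counts used as the empirical topic prior.
// [[Rcpp::export(name = ".lda_gibbs_fit")]]
List lda_gibbs_fit(List docs, int K, int V, double alpha, double beta,
                   int n_iter, int seed) {
  const int D = docs.size();
  DetRNG rng(static_cast<uint64_t>(seed) * 2654435761ULL + 17ULL);

  std::vector<std::vector<int>> w(D);
  std::vector<std::vector<int>> z(D);
  std::vector<int> nwk(static_cast<size_t>(V) * K, 0);  // word-topic
  std::vector<int> ndk(static_cast<size_t>(D) * K, 0);  // doc-topic
  std::vector<long> nk(K, 0);                           // topic totals

  for (int d = 0; d < D; ++d) {
    IntegerVector doc = docs[d];
    w[d].assign(doc.begin(), doc.end());
    z[d].resize(w[d].size());
    for (size_t i = 0; i < w[d].size(); ++i) {
      int k = rng.below(K);
      z[d][i] = k;
      ++nwk[static_cast<size_t>(w[d][i]) * K + k];
      ++ndk[static_cast<size_t>(d) * K + k];
      ++nk[k];
    }
  }

  std::vector<double> p(K);
  const double Vbeta = V * beta;
  for (int it = 0; it < n_iter; ++it) {
    for (int d = 0; d < D; ++d) {
      int* ndk_d = &ndk[static_cast<size_t>(d) * K];
      for (size_t i = 0; i < w[d].size(); ++i) {
        const int v = w[d][i];
        int k = z[d][i];
        int* nwk_v = &nwk[static_cast<size_t>(v) * K];
        --nwk_v[k]; --ndk_d[k]; --nk[k];
        double tot = 0.0;
        for (int kk = 0; kk < K; ++kk) {
          tot += (nwk_v[kk] + beta) / (nk[kk] + Vbeta) * (ndk_d[kk] + alpha);
          p[kk] = tot;
        }
        const double u = rng.unif() * tot;
        int knew = 0;
        while (knew < K - 1 && p[knew] < u) ++knew;
        z[d][i] = knew;
        ++nwk_v[knew]; ++ndk_d[knew]; ++nk[knew];
      }
    }
  }

  NumericMatrix phi(K, V);
  for (int v = 0; v < V; ++v)
    for (int k = 0; k < K; ++k)
      phi(k, v) = (nwk[static_cast<size_t>(v) * K + k] + beta) / (nk[k] + Vbeta);

  NumericMatrix theta(D, K);
  for (int d = 0; d < D; ++d) {
    double tot = 0.0;
    for (int k = 0; k < K; ++k) tot += ndk[static_cast<size_t>(d) * K + k] + alpha;
    for (int k = 0; k < K; ++k)
      theta(d, k) = (ndk[static_cast<size_t>(d) * K + k] + alpha) / tot;
  }

  NumericVector nk_out(K);
  for (int k = 0; k < K; ++k) nk_out[k] = static_cast<double>(nk[k]);

  return List::create(_["phi"] = phi, _["theta"] = theta,
                      _["topic_counts"] = nk_out);
}

// Fold-in inference for unseen documents with a fixed topic-word matrix.
// Counts are averaged over the post-burn-in iterations.
// [[Rcpp::export(name = ".lda_gibbs_infer")]]
NumericMatrix lda_gibbs_infer(NumericMatrix phi, List docs, double alpha,
                              int n_iter, int seed) {
  const int K = phi.nrow();
  const int D = docs.size();
  const int burn = n_iter / 2;
  NumericMatrix theta(D, K);
  DetRNG rng(static_cast<uint64_t>(seed) * 0x9E3779B9ULL + 101ULL);

  std::vector<double> p(K);
  for (int d = 0; d < D; ++d) {
    IntegerVector doc = docs[d];
    const int N = doc.size();
    if (N == 0) {
      for (int k = 0; k < K; ++k) theta(d, k) = 1.0 / K;
      continue;
    }
    std::vector<int> zd(N);
    std::vector<int> ndk(K, 0);
    std::vector<double> acc(K, 0.0);
    for (int i = 0; i < N; ++i) {
      int k = rng.below(K);
      zd[i] = k; ++ndk[k];
    }
    int n_acc = 0;
    for (int it = 0; it < n_iter; ++it) {
      for (int i = 0; i < N; ++i) {
        const int v = doc[i];
        --ndk[zd[i]];
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          tot += phi(k, v) * (ndk[k] + alpha);
          p[k] = tot;
        }
        const double u = rng.unif() * tot;
        int knew = 0;
        while (knew < K - 1 && p[knew] < u) ++knew;
        zd[i] = knew; ++ndk[knew];
      }
      if (it >= burn) {
        for (int k = 0; k < K; ++k) acc[k] += ndk[k] + alpha;
        ++n_acc;
      }
    }
    double tot = 0.0;
    for (int k = 0; k < K; ++k) tot += acc[k];
    for (int k = 0; k < K; ++k) theta(d, k) = acc[k] / tot;
    (void)n_acc;
  }
  return theta;
}
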