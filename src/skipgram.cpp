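#include <Rcpp.h>
#include "rng.h"

using namespace Rcpp;

// Skip-gram with negative sampling, trained single-threaded so that a fixed
// seed gives bit-identical embeddings. docs hold 0-based vocabulary ids;
// sentences are the context units (windows do not cross them).
// [[Rcpp::export(name = ".sgns_train")]]
NumericMatrix sgns_train(List sentences, int V, int dim, int window,
                         int negative, int epochs, double lr, int seed) {
  DetRNG rng(static_cast<uint64_t>(seed) * 0xD1B54A32D192ED03ULL + 7ULL);

  // unigram^0.75 negative-sampling table
  std::vector<double> freq(V, 0.0);
  long total_tokens = 0;
  const int S = sentences.size();
  for (int s = 0; s < S; ++s) {
    IntegerVector sent = sentences[s];
    for (int i = 0; i < sent.size(); ++i) ++freq[sent[i]];
    total_tokens += sent.size();
  }
  const int table_size = 100000;
  std::vector<int> neg_table(table_size);
  {
    double z = 0.0;
    for (int v = 0; v < V; ++v) z += std::pow(freq[v], 0.75);
    double cum = std::pow(freq[0], 0.75) / z;
    int v = 0;
    for (int i = 0; i < table_size; ++i) {
      neg_table[i] = v;
      if ((i + 1.0) / table_size > cum && v < V - 1) {
        ++v;
        cum += std::pow(freq[v], 0.75) / z;
      }
    }
  }

  std::vector<double> syn0(static_cast<size_t>(V) * dim);
  std::vector<double> syn1(static_cast<size_t>(V) * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  std::vector<double> grad(dim);
  const long total_steps = std::max<long>(1, epochs * total_tokens);
  long step = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < S; ++s) {
      IntegerVector sent = sentences[s];
      const int N = sent.size();
      for (int i = 0; i < N; ++i, ++step) {
        const double alpha =
            std::max(lr * (1.0 - static_cast<double>(step) / total_steps),
                     lr * 1e-4);
        const int b = rng.below(window) + 1;  // dynamic window
        const int center = sent[i];
        double* v_in = &syn0[static_cast<size_t>(center) * dim];
        for (int j = std::max(0, i - b); j <= std::min(N - 1, i + b); ++j) {
          if (j == i) continue;
          const int ctx = sent[j];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int neg = 0; neg <= negative; ++neg) {
            int target;
            double label;
            if (neg == 0) {
              target = ctx; label = 1.0;
            } else {
              target = neg_table[rng.below(table_size)];
              if (target == ctx) continue;
              label = 0.0;
            }
            double* v_out = &syn1[static_cast<size_t>(target) * dim];
            double dot = 0.0;
            for (int k = 0; k < dim; ++k) dot += v_in[k] * v_out[k];
            const double pred = 1.0 / (1.0 + std::exp(-dot));
            const double g = (label - pred) * alpha;
            for (int k = 0; k < dim; ++k) {
              grad[k] += g * v_out[k];
              v_out[k] += g * v_in[k];
            }
          }
          for (int k = 0; k < dim; ++k) v_in[k] += grad[k];
        }
      }
    }
  }

  NumericMatrix out(V, dim);
  for (int v = 0; v < V; ++v)
    for (int k = 0; k < dim; ++k)
      out(v, k) = syn0[static_cast<size_t>(v) * dim + k];
  return out;
}
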