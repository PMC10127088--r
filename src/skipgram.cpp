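#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Skip-gram with negative sampling, single-threaded with a private
// xorshift64* RNG so training is bit-reproducible from the seed.

namespace {

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

} // namespace

// sentences: list of integer vectors with 1-based token ids in 1..vocab_size
// Returns vocab_size x dim matrix of input (center-word) vectors.
// [[Rcpp::export(name = ".sgns_train")]]
NumericMatrix sgns_train(List sentences, int vocab_size, int dim, int window,
                         int epochs, int negative, double alpha,
                         double alpha_min, int seed) {
  std::vector<std::vector<int>> sents(sentences.size());
  std::vector<double> counts(vocab_size, 0.0);
  long long total_tokens = 0;
  for (int i = 0; i < sentences.size(); ++i) {
    IntegerVector sv = sentences[i];
    sents[i].resize(sv.size());
    for (int j = 0; j < sv.size(); ++j) {
      int id = sv[j] - 1;
      if (id < 0 || id >= vocab_size) stop("token id out of range");
      sents[i][j] = id;
      counts[id] += 1.0;
      ++total_tokens;
    }
  }
  if (total_tokens == 0) stop("empty corpus");

  // unigram^0.75 table for negative sampling
  const int table_size = 1 << 17;
  std::vector<int> table(table_size);
  double z = 0.0;
  for (int v = 0; v < vocab_size; ++v) z += std::pow(counts[v], 0.75);
  {
    int v = 0;
    double cum = std::pow(counts[0], 0.75) / z;
    for (int t = 0; t < table_size; ++t) {
      table[t] = v;
      if ((t + 1.0) / table_size > cum && v < vocab_size - 1) {
        ++v;
        cum += std::pow(counts[v], 0.75) / z;
      }
    }
  }

  Rng rng(static_cast<uint64_t>(seed));
  std::vector<double> syn0(static_cast<size_t>(vocab_size) * dim);
  std::vector<double> syn1(static_cast<size_t>(vocab_size) * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  std::vector<double> grad(dim);
  long long total_pairs_est = 0;
  for (auto &s : sents)
    total_pairs_est += static_cast<long long>(s.size());
  total_pairs_est *= epochs;
  long long seen = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (auto &s : sents) {
      int n = static_cast<int>(s.size());
      for (int c = 0; c < n; ++c) {
        double lr = alpha - (alpha - alpha_min) *
          (static_cast<double>(seen) / std::max(1LL, total_pairs_est));
        ++seen;
        int b = 1 + rng.below(window);   // dynamic window, word2vec-style
        int center = s[c];
        double *v_c = &syn0[static_cast<size_t>(center) * dim];
        for (int off = -b; off <= b; ++off) {
          if (off == 0) continue;
          int cj = c + off;
          if (cj < 0 || cj >= n) continue;
          int ctx = s[cj];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int d = 0; d <= negative; ++d) {
            int target;
            double label;
            if (d == 0) { target = ctx; label = 1.0; }
            else {
              target = table[rng.below(table_size)];
              if (target == ctx) continue;
              label = 0.0;
            }
            double *v_o = &syn1[static_cast<size_t>(target) * dim];
            double dot = 0.0;
            for (int k = 0; k < dim; ++k) dot += v_c[k] * v_o[k];
            double g = (label - sigmoid(dot)) * lr;
            for (int k = 0; k < dim; ++k) {
              grad[k] += g * v_o[k];
              v_o[k] += g * v_c[k];
            }
          }
          for (int k = 0; k < dim; ++k) v_c[k] += grad[k];
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix out(vocab_size, dim);
  for (int v = 0; v < vocab_size; ++v)
    for (int k = 0; k < dim; ++k)
      out(v, k) = syn0[static_cast<size_t>(v) * dim + k];
  return out;
}
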