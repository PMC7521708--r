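// Skip-gram with negative sampling over a random-walk corpus.
// Single-threaded, own RNG -> bitwise reproducible for a given seed.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed * 2654435761ULL + 1ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 2685821657736338717ULL;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

inline double sigmoidf(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

} // namespace

// tokens: 0-based node indices, all walks concatenated
// starts: 0-based walk start offsets, length n_walks + 1 (last = n_tokens)
// [[Rcpp::export]]
NumericMatrix sgns_train(IntegerVector tokens, IntegerVector starts,
                         int vocab, int dim, int window, int epochs,
                         int negative, double alpha, int seed) {
  const int n_tokens = tokens.size();
  const int n_walks = starts.size() - 1;
  if (vocab <= 0 || dim <= 0 || n_tokens == 0)
    stop("empty corpus or invalid dimensions");

  // unigram^0.75 cumulative table for negative sampling
  std::vector<double> cnt(vocab, 0.0);
  for (int i = 0; i < n_tokens; ++i) cnt[tokens[i]] += 1.0;
  std::vector<double> cum(vocab);
  double tot = 0.0;
  for (int v = 0; v < vocab; ++v) { tot += std::pow(cnt[v], 0.75); cum[v] = tot; }
  for (int v = 0; v < vocab; ++v) cum[v] /= tot;

  XorShift rng(static_cast<uint64_t>(seed));
  std::vector<float> syn0(static_cast<size_t>(vocab) * dim);
  std::vector<float> syn1(static_cast<size_t>(vocab) * dim, 0.0f);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  std::vector<float> neu1e(dim);
  const double total_steps = static_cast<double>(epochs) * n_tokens;
  double processed = 0.0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int w = 0; w < n_walks; ++w) {
      const int beg = starts[w], end = starts[w + 1];
      for (int c = beg; c < end; ++c, processed += 1.0) {
        const double lr =
          alpha * std::max(1e-4, 1.0 - processed / total_steps);
        const int center = tokens[c];
        const int shrink = static_cast<int>(rng.next() % window);
        for (int off = -(window - shrink); off <= window - shrink; ++off) {
          if (off == 0) continue;
          const int pos = c + off;
          if (pos < beg || pos >= end) continue;
          const int input = tokens[pos];
          float* l1 = &syn0[static_cast<size_t>(input) * dim];
          std::fill(neu1e.begin(), neu1e.end(), 0.0f);
          for (int d = 0; d <= negative; ++d) {
            int target; double label;
            if (d == 0) { target = center; label = 1.0; }
            else {
              const double u = rng.unif();
              target = static_cast<int>(
                std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
              if (target >= vocab) target = vocab - 1;
              if (target == center) continue;
              label = 0.0;
            }
            float* l2 = &syn1[static_cast<size_t>(target) * dim];
            float f = 0.0f;
            for (int k = 0; k < dim; ++k) f += l1[k] * l2[k];
            const float g = static_cast<float>((label - sigmoidf(f)) * lr);
            for (int k = 0; k < dim; ++k) neu1e[k] += g * l2[k];
            for (int k = 0; k < dim; ++k) l2[k] += g * l1[k];
          }
          for (int k = 0; k < dim; ++k) l1[k] += neu1e[k];
        }
      }
    }
  }

  NumericMatrix out(vocab, dim);
  for (int v = 0; v < vocab; ++v)
    for (int k = 0; k < dim; ++k)
      out(v, k) = syn0[static_cast<size_t>(v) * dim + k];
  return out;
}
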