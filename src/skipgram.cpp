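// Skip-gram word embeddings with negative sampling, trained by SGD.
// Self-contained xorshift RNG so a fixed seed gives bit-identical vectors
// regardless of R's RNG state; single-threaded by design.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12;
    s ^= s << 25;
    s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

} // namespace

// tokens: 0-based vocabulary ids, -1 marks a document boundary.
// counts: per-id corpus frequencies (for the unigram^0.75 sampling table).
// [[Rcpp::export]]
NumericMatrix skipgram_train_cpp(IntegerVector tokens, int vocab_size,
                                 NumericVector counts, int dim, int window,
                                 int negative, int epochs, double alpha,
                                 int seed) {
  const int n = tokens.size();
  XorShift rng((uint64_t)seed * 2654435761ULL + 1ULL);

  // cumulative table for unigram^0.75 negative sampling
  std::vector<double> cum(vocab_size);
  double tot = 0.0;
  for (int v = 0; v < vocab_size; ++v) {
    tot += std::pow(counts[v], 0.75);
    cum[v] = tot;
  }

  std::vector<double> W((size_t)vocab_size * dim);
  std::vector<double> C((size_t)vocab_size * dim, 0.0);
  for (size_t i = 0; i < W.size(); ++i)
    W[i] = (rng.unif() - 0.5) / dim;

  // per-position document bounds so context windows never cross documents
  std::vector<int> doc_lo(n), doc_hi(n);
  {
    int lo = 0;
    for (int i = 0; i < n; ++i) {
      if (tokens[i] < 0) lo = i + 1;
      doc_lo[i] = lo;
    }
    int hi = n - 1;
    for (int i = n - 1; i >= 0; --i) {
      if (tokens[i] < 0) hi = i - 1;
      doc_hi[i] = hi;
    }
  }

  long long total_steps = (long long)epochs * n;
  long long step = 0;
  std::vector<double> grad(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = 0; i < n; ++i, ++step) {
      int w = tokens[i];
      if (w < 0) continue;
      double lr = alpha * (1.0 - (double)step / (double)(total_steps + 1));
      if (lr < alpha * 1e-4) lr = alpha * 1e-4;
      int b = 1 + rng.below(window); // dynamic window, as in word2vec
      int jmin = std::max(i - b, doc_lo[i]);
      int jmax = std::min(i + b, doc_hi[i]);
      for (int j = jmin; j <= jmax; ++j) {
        if (j == i) continue;
        int c = tokens[j];
        double *vw = &W[(size_t)w * dim];
        std::fill(grad.begin(), grad.end(), 0.0);
        for (int k = 0; k <= negative; ++k) {
          int target;
          double label;
          if (k == 0) {
            target = c;
            label = 1.0;
          } else {
            double u = rng.unif() * tot;
            int lo = 0, hi = vocab_size - 1;
            while (lo < hi) {
              int mid = (lo + hi) / 2;
              if (cum[mid] < u) lo = mid + 1; else hi = mid;
            }
            target = lo;
            if (target == c) continue;
            label = 0.0;
          }
          double *vc = &C[(size_t)target * dim];
          double dot = 0.0;
          for (int d = 0; d < dim; ++d) dot += vw[d] * vc[d];
          double g = (label - sigmoid(dot)) * lr;
          for (int d = 0; d < dim; ++d) {
            grad[d] += g * vc[d];
            vc[d] += g * vw[d];
          }
        }
        for (int d = 0; d < dim; ++d) vw[d] += grad[d];
      }
    }
  }

  NumericMatrix out(vocab_size, dim);
  for (int v = 0; v < vocab_size; ++v)
    for (int d = 0; d < dim; ++d)
      out(v, d) = W[(size_t)v * dim + d];
  return out;
}
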