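#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Self-contained RNG (xorshift64*) so training is bit-reproducible from the
// seed alone, independent of R's RNG state.
namespace {

struct XorShift {
  uint64_t state;
  explicit XorShift(uint64_t seed) : state(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    uint64_t x = state;
    x ^= x >> 12;
    x ^= x << 25;
    x ^= x >> 27;
    state = x;
    return x * 0x2545F4914F6CDD1DULL;
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in [0, n)
  uint64_t below(uint64_t n) { return next() % n; }
};

inline double sigmoid(double x) {
  if (x > 30.0) return 1.0;
  if (x < -30.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

} // namespace

//' CBOW word2vec training with negative sampling (internal).
//'
//' @param sentences list of integer vectors, word ids in 1..vocab_size
//' @param vocab_size number of distinct words
//' @param dim embedding dimension
//' @param window one-sided context width (actual width sampled per position)
//' @param epochs passes over the corpus
//' @param negative negative samples per target
//' @param alpha initial learning rate (linearly decayed)
//' @param seed RNG seed
//' @return numeric matrix vocab_size x dim (input embeddings)
//' @noRd
// [[Rcpp::export]]
NumericMatrix cbow_train_cpp(List sentences, int vocab_size, int dim,
                             int window, int epochs, int negative,
                             double alpha, int seed) {
  XorShift rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);

  // word frequencies for the negative-sampling unigram table (freq^0.75)
  std::vector<double> freq(vocab_size, 0.0);
  long long total_tokens = 0;
  int n_sent = sentences.size();
  std::vector<std::vector<int>> corpus(n_sent);
  for (int s = 0; s < n_sent; ++s) {
    IntegerVector sv = sentences[s];
    corpus[s].assign(sv.begin(), sv.end());
    for (int w : corpus[s]) {
      freq[w - 1] += 1.0;
      ++total_tokens;
    }
  }
  const int table_size = 100000;
  std::vector<int> table(table_size);
  {
    double z = 0.0;
    for (int v = 0; v < vocab_size; ++v) z += std::pow(freq[v], 0.75);
    double cum = std::pow(freq[0], 0.75) / z;
    int v = 0;
    for (int i = 0; i < table_size; ++i) {
      table[i] = v;
      if ((i + 1.0) / table_size > cum && v < vocab_size - 1) {
        ++v;
        cum += std::pow(freq[v], 0.75) / z;
      }
    }
  }

  // syn0: input embeddings, syn1: output (negative-sampling) weights
  std::vector<double> syn0(static_cast<size_t>(vocab_size) * dim);
  std::vector<double> syn1(static_cast<size_t>(vocab_size) * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  std::vector<double> neu1(dim), neu1e(dim);
  const double min_alpha = alpha * 1e-4;
  long long processed = 0;
  const long long budget = total_tokens * static_cast<long long>(epochs);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < n_sent; ++s) {
      const std::vector<int>& sent = corpus[s];
      int len = static_cast<int>(sent.size());
      for (int t = 0; t < len; ++t) {
        double lr = alpha * (1.0 - static_cast<double>(processed) / (budget + 1));
        if (lr < min_alpha) lr = min_alpha;
        ++processed;

        int b = static_cast<int>(rng.below(static_cast<uint64_t>(window)));
        int lo = t - window + b, hi = t + window - b;
        if (lo < 0) lo = 0;
        if (hi > len - 1) hi = len - 1;
        int cw = 0;
        std::fill(neu1.begin(), neu1.end(), 0.0);
        for (int c = lo; c <= hi; ++c) {
          if (c == t) continue;
          const double* v = &syn0[static_cast<size_t>(sent[c] - 1) * dim];
          for (int k = 0; k < dim; ++k) neu1[k] += v[k];
          ++cw;
        }
        if (cw == 0) continue;
        for (int k = 0; k < dim; ++k) neu1[k] /= cw;
        std::fill(neu1e.begin(), neu1e.end(), 0.0);

        int word = sent[t] - 1;
        for (int d = 0; d <= negative; ++d) {
          int target;
          double label;
          if (d == 0) {
            target = word;
            label = 1.0;
          } else {
            target = table[rng.below(table_size)];
            if (target == word) continue;
            label = 0.0;
          }
          double* o = &syn1[static_cast<size_t>(target) * dim];
          double f = 0.0;
          for (int k = 0; k < dim; ++k) f += neu1[k] * o[k];
          double g = (label - sigmoid(f)) * lr;
          for (int k = 0; k < dim; ++k) {
            neu1e[k] += g * o[k];
            o[k] += g * neu1[k];
          }
        }
        for (int c = lo; c <= hi; ++c) {
          if (c == t) continue;
          double* v = &syn0[static_cast<size_t>(sent[c] - 1) * dim];
          for (int k = 0; k < dim; ++k) v[k] += neu1e[k];
        }
      }
    }
  }

  NumericMatrix out(vocab_size, dim);
  for (int v = 0; v < vocab_size; ++v)
    for (int k = 0; k < dim; ++k)
      out(v, k) = syn0[static_cast<size_t>(v) * dim + k];
  return out;
}
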