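// Skip-gram with negative sampling, single-threaded and deterministic for a
// given seed. Sentences arrive as 0-based word-id vectors (OOV already
// removed); the unigram table uses the standard 0.75 power smoothing.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 88172645463325252ULL) {}
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s;
  }
  // uniform in [0, n)
  uint64_t next_below(uint64_t n) { return next() % n; }
  double next_unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

} // namespace

// [[Rcpp::export(name = ".sgns_train")]]
NumericMatrix sgns_train(List sentences, NumericVector counts, int dim,
                         int window, int epochs, int negative,
                         double alpha0, int seed) {
  const int vocab = counts.size();
  if (vocab == 0) stop("empty vocabulary");
  XorShift rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);

  // negative-sampling table, counts^0.75
  const int table_size = 1 << 17;
  std::vector<int> table(table_size);
  {
    std::vector<double> pw(vocab);
    double total = 0.0;
    for (int i = 0; i < vocab; ++i) { pw[i] = std::pow(counts[i], 0.75); total += pw[i]; }
    double cum = pw[0] / total;
    int w = 0;
    for (int i = 0; i < table_size; ++i) {
      table[i] = w;
      if ((i + 1.0) / table_size > cum && w < vocab - 1) {
        ++w;
        cum += pw[w] / total;
      }
    }
  }

  std::vector<double> syn0(static_cast<size_t>(vocab) * dim);
  std::vector<double> syn1(static_cast<size_t>(vocab) * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i) {
    syn0[i] = (rng.next_unif() - 0.5) / dim;
  }

  // total training words for the linear learning-rate decay
  long long total_words = 0;
  const int n_sent = sentences.size();
  std::vector<IntegerVector> sents(n_sent);
  for (int s = 0; s < n_sent; ++s) {
    sents[s] = as<IntegerVector>(sentences[s]);
    total_words += sents[s].size();
  }
  if (total_words == 0) stop("no training tokens");
  const double alpha_min = alpha0 * 1e-4;
  long long processed = 0;
  std::vector<double> grad(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < n_sent; ++s) {
      const IntegerVector& sent = sents[s];
      const int len = sent.size();
      for (int pos = 0; pos < len; ++pos) {
        double alpha = alpha0 * (1.0 - static_cast<double>(processed) /
                                       (static_cast<double>(total_words) * epochs + 1.0));
        if (alpha < alpha_min) alpha = alpha_min;
        ++processed;
        const int center = sent[pos];
        const int reduced = 1 + static_cast<int>(rng.next_below(window));
        for (int off = -reduced; off <= reduced; ++off) {
          if (off == 0) continue;
          const int cpos = pos + off;
          if (cpos < 0 || cpos >= len) continue;
          const int context = sent[cpos];
          double* v_in = &syn0[static_cast<size_t>(center) * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int neg = 0; neg <= negative; ++neg) {
            int target; double label;
            if (neg == 0) { target = context; label = 1.0; }
            else {
              target = table[rng.next_below(table_size)];
              if (target == context) continue;
              label = 0.0;
            }
            double* v_out = &syn1[static_cast<size_t>(target) * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += v_in[d] * v_out[d];
            const double g = (label - sigmoid(dot)) * alpha;
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * v_out[d];
              v_out[d] += g * v_in[d];
            }
          }
          for (int d = 0; d < dim; ++d) v_in[d] += grad[d];
        }
      }
    }
  }

  NumericMatrix out(vocab, dim);
  for (int i = 0; i < vocab; ++i) {
    for (int d = 0; d < dim; ++d) out(i, d) = syn0[static_cast<size_t>(i) * dim + d];
  }
  return out;
}
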