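// Skip-gram with negative sampling over random-walk corpora.
// Single-threaded on purpose: results are bit-reproducible for a given seed
// (own splitmix64 RNG, no dependence on the C++ stdlib's distributions).
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

namespace {

struct SplitMix64 {
  uint64_t state;
  explicit SplitMix64(uint64_t s) : state(s) {}
  uint64_t next() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in [0, n)
  int unif_int(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

inline double sigmoid(double x) {
  if (x > 6.0) return 1.0 - 1e-9;
  if (x < -6.0) return 1e-9;
  return 1.0 / (1.0 + std::exp(-x));
}

}  // namespace

// [[Rcpp::export]]
List sgns_train_cpp(List walks, int n_nodes, int dim, int window, int negative,
                    int epochs, double alpha0, double seed) {
  std::vector<std::vector<int>> corpus;
  corpus.reserve(walks.size());
  long long total_tokens = 0;
  std::vector<double> counts(n_nodes, 0.0);
  for (R_xlen_t i = 0; i < walks.size(); ++i) {
    IntegerVector w = walks[i];
    std::vector<int> v(w.begin(), w.end());
    for (int x : v) {
      if (x < 0 || x >= n_nodes) stop("walk token out of range");
      counts[x] += 1.0;
    }
    total_tokens += static_cast<long long>(v.size());
    corpus.push_back(std::move(v));
  }
  if (total_tokens == 0) stop("empty walk corpus");

  // unigram^0.75 noise distribution, sampled by binary search on the CDF
  std::vector<double> noise_cdf(n_nodes, 0.0);
  double acc = 0.0;
  for (int i = 0; i < n_nodes; ++i) {
    acc += std::pow(counts[i], 0.75);
    noise_cdf[i] = acc;
  }
  if (acc <= 0) stop("no observed node");

  SplitMix64 rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);

  std::vector<double> syn0(static_cast<size_t>(n_nodes) * dim);
  std::vector<double> syn1(static_cast<size_t>(n_nodes) * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i) {
    syn0[i] = (rng.unif() - 0.5) / dim;
  }

  const double total_steps = static_cast<double>(epochs) * total_tokens + 1.0;
  long long processed = 0;
  NumericVector epoch_loss(epochs);
  std::vector<double> grad(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    double loss_sum = 0.0;
    long long loss_n = 0;
    for (const auto& walk : corpus) {
      const int len = static_cast<int>(walk.size());
      for (int pos = 0; pos < len; ++pos) {
        const int center = walk[pos];
        ++processed;
        double alpha = alpha0 * (1.0 - processed / total_steps);
        if (alpha < alpha0 * 1e-4) alpha = alpha0 * 1e-4;
        const int b = rng.unif_int(window);  // reduced-window subsampling
        const int lo = pos - (window - b) < 0 ? 0 : pos - (window - b);
        const int hi = pos + (window - b) >= len ? len - 1 : pos + (window - b);
        for (int c = lo; c <= hi; ++c) {
          if (c == pos) continue;
          const int context = walk[c];
          double* v = &syn0[static_cast<size_t>(context) * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int d = 0; d <= negative; ++d) {
            int target;
            double label;
            if (d == 0) {
              target = center;
              label = 1.0;
            } else {
              const double u = rng.unif() * acc;
              target = static_cast<int>(
                  std::lower_bound(noise_cdf.begin(), noise_cdf.end(), u) -
                  noise_cdf.begin());
              if (target >= n_nodes) target = n_nodes - 1;
              if (target == center) continue;
              label = 0.0;
            }
            double* u1 = &syn1[static_cast<size_t>(target) * dim];
            double dot = 0.0;
            for (int k = 0; k < dim; ++k) dot += v[k] * u1[k];
            const double pred = sigmoid(dot);
            loss_sum += label > 0.5 ? -std::log(pred) : -std::log(1.0 - pred);
            ++loss_n;
            const double g = (label - pred) * alpha;
            for (int k = 0; k < dim; ++k) {
              grad[k] += g * u1[k];
              u1[k] += g * v[k];
            }
          }
          for (int k = 0; k < dim; ++k) v[k] += grad[k];
        }
      }
    }
    epoch_loss[ep] = loss_n > 0 ? loss_sum / loss_n : NA_REAL;
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix emb(n_nodes, dim);
  for (int i = 0; i < n_nodes; ++i) {
    for (int k = 0; k < dim; ++k) emb(i, k) = syn0[static_cast<size_t>(i) * dim + k];
  }
  return List::create(_["embedding"] = emb, _["epoch_loss"] = epoch_loss);
}
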