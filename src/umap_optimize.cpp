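// Stochastic gradient layout optimizer for the UMAP embedding.
// Single-threaded with an internal xorshift128+ RNG so that runs are
// bit-reproducible for a given seed, independent of R's RNG state.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Xorshift128p {
  uint64_t s0, s1;
  explicit Xorshift128p(uint64_t seed) {
    // splitmix64 to spread the seed
    uint64_t z = seed + 0x9E3779B97F4A7C15ULL;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    s0 = z ^ (z >> 31);
    z = seed + 2 * 0x9E3779B97F4A7C15ULL;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    s1 = z ^ (z >> 31);
    if (s0 == 0 && s1 == 0) s1 = 1;
  }
  uint64_t next() {
    uint64_t x = s0;
    const uint64_t y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  int next_int(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

inline double clip4(double v) {
  if (v > 4.0) return 4.0;
  if (v < -4.0) return -4.0;
  return v;
}

} // namespace

// [[Rcpp::export]]
NumericMatrix umap_optimize_layout(NumericMatrix init, IntegerVector head,
                                   IntegerVector tail, NumericVector epochs_per_sample,
                                   double a, double b, int n_epochs,
                                   double initial_alpha, int negative_sample_rate,
                                   double seed) {
  NumericMatrix emb = clone(init);
  const int n = emb.nrow();
  const int dim = emb.ncol();
  const int n_edges = head.size();
  Xorshift128p rng(static_cast<uint64_t>(seed));

  std::vector<double> eons(epochs_per_sample.begin(), epochs_per_sample.end());
  std::vector<double> epn(n_edges), eonns(n_edges);
  for (int i = 0; i < n_edges; ++i) {
    epn[i] = epochs_per_sample[i] / negative_sample_rate;
    eonns[i] = epn[i];
  }

  for (int epoch = 0; epoch < n_epochs; ++epoch) {
    const double alpha = initial_alpha * (1.0 - static_cast<double>(epoch) / n_epochs);
    for (int e = 0; e < n_edges; ++e) {
      if (eons[e] > epoch) continue;
      const int j = head[e];
      const int k = tail[e];
      double dist2 = 0.0;
      for (int d = 0; d < dim; ++d) {
        const double diff = emb(j, d) - emb(k, d);
        dist2 += diff * diff;
      }
      double grad_coeff = 0.0;
      if (dist2 > 0.0) {
        const double pd = std::pow(dist2, b);
        grad_coeff = (-2.0 * a * b * pd / dist2) / (a * pd + 1.0);
      }
      for (int d = 0; d < dim; ++d) {
        const double g = clip4(grad_coeff * (emb(j, d) - emb(k, d)));
        emb(j, d) += alpha * g;
        emb(k, d) -= alpha * g;
      }
      eons[e] += epochs_per_sample[e];

      const int n_neg = static_cast<int>((epoch - eonns[e]) / epn[e]);
      for (int p = 0; p < n_neg; ++p) {
        const int k2 = rng.next_int(n);
        if (k2 == j) continue;
        double d2 = 0.0;
        for (int d = 0; d < dim; ++d) {
          const double diff = emb(j, d) - emb(k2, d);
          d2 += diff * diff;
        }
        double gc;
        if (d2 > 0.0) {
          gc = (2.0 * b) / ((0.001 + d2) * (a * std::pow(d2, b) + 1.0));
        } else {
          gc = 0.0;
        }
        for (int d = 0; d < dim; ++d) {
          double g;
          if (gc > 0.0) {
            g = clip4(gc * (emb(j, d) - emb(k2, d)));
          } else {
            g = 4.0;
          }
          emb(j, d) += alpha * g;
        }
      }
      eonns[e] += n_neg * epn[e];
    }
  }
  return emb;
}
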