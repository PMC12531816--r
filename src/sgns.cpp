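#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Skip-gram with negative sampling over integer-coded sentences.
// Canonical word2vec update rule: linear learning-rate decay, dynamic
// window shrink, unigram^0.75 negative-sampling table, logit clipping
// at |f| = 6. Single-threaded; fully deterministic for a fixed seed.
// [[Rcpp::export(name = ".train_sgns_cpp")]]
NumericMatrix train_sgns_cpp(List sentences, NumericVector vocab_freq,
                             int dim, int window, int negative, int epochs,
                             double alpha0, double min_alpha,
                             unsigned int seed) {
  int V = vocab_freq.size();
  if (V < 1) stop("empty vocabulary");
  if (dim < 1) stop("dim must be >= 1");
  if (window < 1) stop("window must be >= 1");

  const int table_size = 1000000;
  std::vector<int> table(table_size);
  {
    double total = 0.0;
    std::vector<double> pw(V);
    for (int i = 0; i < V; ++i) {
      pw[i] = std::pow((double)vocab_freq[i], 0.75);
      total += pw[i];
    }
    int i = 0;
    double d1 = pw[0] / total;
    for (int a = 0; a < table_size; ++a) {
      table[a] = i;
      if ((double)a / table_size > d1 && i < V - 1) {
        ++i;
        d1 += pw[i] / total;
      }
    }
  }

  unsigned long long rng = (unsigned long long)seed;
  if (rng == 0) rng = 1;
  std::vector<float> syn0((size_t)V * dim);
  std::vector<float> syn1((size_t)V * dim, 0.0f);
  for (size_t i = 0; i < syn0.size(); ++i) {
    rng = rng * 25214903917ULL + 11ULL;
    syn0[i] = (((rng & 0xFFFFULL) / 65536.0f) - 0.5f) / dim;
  }

  int S = sentences.size();
  std::vector<std::vector<int> > sen(S);
  long long total_words = 0;
  for (int s = 0; s < S; ++s) {
    IntegerVector v = sentences[s];
    sen[s].assign(v.begin(), v.end());
    for (int j = 0; j < v.size(); ++j)
      if (v[j] < 0 || v[j] >= V) stop("token id out of range");
    total_words += v.size();
  }
  long long train_total = total_words * (long long)epochs + 1;
  long long words_done = 0;

  std::vector<float> neu1e(dim);
  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < S; ++s) {
      const std::vector<int>& w = sen[s];
      int len = (int)w.size();
      for (int pos = 0; pos < len; ++pos) {
        double alpha = alpha0 * (1.0 - (double)words_done / (double)train_total);
        if (alpha < min_alpha) alpha = min_alpha;
        ++words_done;
        int center = w[pos];
        rng = rng * 25214903917ULL + 11ULL;
        int b = (int)(rng % (unsigned long long)window);
        for (int a = b; a < window * 2 + 1 - b; ++a) {
          if (a == window) continue;
          int c = pos - window + a;
          if (c < 0 || c >= len) continue;
          int ctx = w[c];
          float* v0 = &syn0[(size_t)ctx * dim];
          std::fill(neu1e.begin(), neu1e.end(), 0.0f);
          for (int d = 0; d < negative + 1; ++d) {
            int target, label;
            if (d == 0) {
              target = center;
              label = 1;
            } else {
              rng = rng * 25214903917ULL + 11ULL;
              target = table[(rng >> 16) % table_size];
              if (target == center) continue;
              label = 0;
            }
            float* v1 = &syn1[(size_t)target * dim];
            double f = 0.0;
            for (int j = 0; j < dim; ++j) f += (double)v0[j] * v1[j];
            double g;
            if (f > 6.0) g = (label - 1) * alpha;
            else if (f < -6.0) g = (label - 0) * alpha;
            else g = (label - 1.0 / (1.0 + std::exp(-f))) * alpha;
            for (int j = 0; j < dim; ++j) neu1e[j] += (float)(g * v1[j]);
            for (int j = 0; j < dim; ++j) v1[j] += (float)(g * v0[j]);
          }
          for (int j = 0; j < dim; ++j) v0[j] += neu1e[j];
        }
      }
      if (s % 1024 == 0) Rcpp::checkUserInterrupt();
    }
  }

  NumericMatrix out(V, dim);
  for (int i = 0; i < V; ++i)
    for (int j = 0; j < dim; ++j)
      out(i, j) = syn0[(size_t)i * dim + j];
  return out;
}
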