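// Skip-gram with negative sampling over a walk corpus.
//
// Single-threaded, deterministic for a given seed.  Negative samples come
// from an alias table over unigram counts raised to 3/4.  Learning rate
// decays linearly over processed tokens as in the classic implementation.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct Rng2 {
  std::mt19937_64 gen;
  explicit Rng2(uint64_t seed) : gen(seed) {}
  double unif() { return (gen() >> 11) * (1.0 / 9007199254740992.0); }
  int unif_int(int n) {
    int k = static_cast<int>(unif() * n);
    return k >= n ? n - 1 : k;
  }
};

struct Alias2 {
  std::vector<double> prob;
  std::vector<int> alias;
  void build(const std::vector<double>& w) {
    int n = static_cast<int>(w.size());
    prob.assign(n, 0.0);
    alias.assign(n, 0);
    double tot = 0.0;
    for (double x : w) tot += x;
    std::vector<double> sc(n);
    for (int i = 0; i < n; ++i) sc[i] = w[i] * n / tot;
    std::vector<int> small, large;
    for (int i = 0; i < n; ++i) (sc[i] < 1.0 ? small : large).push_back(i);
    while (!small.empty() && !large.empty()) {
      int s = small.back(); small.pop_back();
      int l = large.back(); large.pop_back();
      prob[s] = sc[s];
      alias[s] = l;
      sc[l] = (sc[l] + sc[s]) - 1.0;
      (sc[l] < 1.0 ? small : large).push_back(l);
    }
    for (int s : small) prob[s] = 1.0;
    for (int l : large) prob[l] = 1.0;
  }
  int draw(Rng2& rng) const {
    int n = static_cast<int>(prob.size());
    int k = static_cast<int>(rng.unif() * n);
    if (k >= n) k = n - 1;
    return (rng.unif() < prob[k]) ? k : alias[k];
  }
};

inline double sigmoid(double x) {
  if (x > 30.0) return 1.0;
  if (x < -30.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

}  // namespace

// walks: list of 0-based integer vectors; returns input (syn0) and output
// (syn1) matrices, n x d.
// [[Rcpp::export]]
List cpp_sgns_train(List walks, int n, int d, int window, int negatives,
                    int epochs, double lr0, double seed) {
  Rng2 rng(static_cast<uint64_t>(seed));

  std::vector<double> cnt(n, 0.0);
  long total_tokens = 0;
  for (int i = 0; i < walks.size(); ++i) {
    IntegerVector wk = walks[i];
    total_tokens += wk.size();
    for (int t = 0; t < wk.size(); ++t) cnt[wk[t]] += 1.0;
  }
  std::vector<double> noise(n);
  for (int i = 0; i < n; ++i) noise[i] = std::pow(cnt[i], 0.75);
  Alias2 neg_tab;
  neg_tab.build(noise);

  std::vector<double> syn0(static_cast<size_t>(n) * d);
  std::vector<double> syn1(static_cast<size_t>(n) * d, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / d;

  const double lr_min = lr0 * 1e-4;
  double total_work = static_cast<double>(total_tokens) * std::max(1, epochs);
  long processed = 0;
  std::vector<double> acc(d);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int wi = 0; wi < walks.size(); ++wi) {
      IntegerVector wk = walks[wi];
      int len = wk.size();
      for (int pos = 0; pos < len; ++pos) {
        double lr = lr0 * (1.0 - processed / (total_work + 1.0));
        if (lr < lr_min) lr = lr_min;
        ++processed;
        int center = wk[pos];
        int b = 1 + rng.unif_int(window);  // dynamic window radius
        for (int off = -b; off <= b; ++off) {
          if (off == 0) continue;
          int pos2 = pos + off;
          if (pos2 < 0 || pos2 >= len) continue;
          int ctx = wk[pos2];  // input word; center is the prediction target
          double* vin = &syn0[static_cast<size_t>(ctx) * d];
          std::fill(acc.begin(), acc.end(), 0.0);
          for (int k = 0; k <= negatives; ++k) {
            int target;
            double label;
            if (k == 0) {
              target = center;
              label = 1.0;
            } else {
              target = neg_tab.draw(rng);
              if (target == center) continue;
              label = 0.0;
            }
            double* vout = &syn1[static_cast<size_t>(target) * d];
            double f = 0.0;
            for (int j = 0; j < d; ++j) f += vin[j] * vout[j];
            double g = (label - sigmoid(f)) * lr;
            for (int j = 0; j < d; ++j) acc[j] += g * vout[j];
            for (int j = 0; j < d; ++j) vout[j] += g * vin[j];
          }
          for (int j = 0; j < d; ++j) vin[j] += acc[j];
        }
      }
    }
  }

  NumericMatrix in_m(n, d), out_m(n, d);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < d; ++j) {
      in_m(i, j) = syn0[static_cast<size_t>(i) * d + j];
      out_m(i, j) = syn1[static_cast<size_t>(i) * d + j];
    }
  return List::create(_["input"] = in_m, _["output"] = out_m,
                      _["counts"] = NumericVector(cnt.begin(), cnt.end()));
}
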