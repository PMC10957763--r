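// Alias-table sampling and multilayer informativeness diffusion.
//
// The walk engine keeps its own 64-bit Mersenne Twister and derives uniforms
// from raw draws so that a given seed yields the same corpus on any platform.
// One alias draw always consumes exactly two uniforms (O(1) per step).

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct Rng {
  std::mt19937_64 gen;
  long draws = 0;
  explicit Rng(uint64_t seed) : gen(seed) {}
  double unif() {
    ++draws;
    // 53-bit uniform in [0, 1)
    return (gen() >> 11) * (1.0 / 9007199254740992.0);
  }
  int unif_int(int n) {  // in [0, n)
    int k = static_cast<int>(unif() * n);
    return k >= n ? n - 1 : k;
  }
};

struct AliasTable {
  std::vector<double> prob;
  std::vector<int> alias;

  void build(const std::vector<double>& w) {
    int n = static_cast<int>(w.size());
    prob.assign(n, 0.0);
    alias.assign(n, 0);
    double tot = 0.0;
    for (double x : w) tot += x;
    std::vector<double> scaled(n);
    for (int i = 0; i < n; ++i) scaled[i] = w[i] * n / tot;
    std::vector<int> small, large;
    small.reserve(n);
    large.reserve(n);
    for (int i = 0; i < n; ++i)
      (scaled[i] < 1.0 ? small : large).push_back(i);
    while (!small.empty() && !large.empty()) {
      int s = small.back(); small.pop_back();
      int l = large.back(); large.pop_back();
      prob[s] = scaled[s];
      alias[s] = l;
      scaled[l] = (scaled[l] + scaled[s]) - 1.0;
      (scaled[l] < 1.0 ? small : large).push_back(l);
    }
    for (int s : small) prob[s] = 1.0;
    for (int l : large) prob[l] = 1.0;
  }

  int draw(Rng& rng) const {
    double u1 = rng.unif(), u2 = rng.unif();
    int n = static_cast<int>(prob.size());
    int k = static_cast<int>(u1 * n);
    if (k >= n) k = n - 1;
    return (u2 < prob[k]) ? k : alias[k];
  }
};

// Compressed adjacency for one undirected layer, neighbours sorted by id.
struct Layer {
  int n;
  std::vector<int> offset;           // n + 1
  std::vector<int> nbr;              // 2|E|
  std::vector<double> w;             // 2|E|
  std::vector<AliasTable> node_tab;  // weight-proportional, per node
  std::vector<AliasTable> edge_tab;  // second-order, per directed edge

  void init(const List& adj_idx, const List& adj_w) {
    n = adj_idx.size();
    offset.assign(n + 1, 0);
    for (int i = 0; i < n; ++i) {
      IntegerVector ni = adj_idx[i];
      offset[i + 1] = offset[i] + ni.size();
    }
    nbr.resize(offset[n]);
    w.resize(offset[n]);
    for (int i = 0; i < n; ++i) {
      IntegerVector ni = adj_idx[i];
      NumericVector wi = adj_w[i];
      for (int t = 0; t < ni.size(); ++t) {
        nbr[offset[i] + t] = ni[t];  // 0-based, ascending
        w[offset[i] + t] = wi[t];
      }
    }
  }

  int degree(int i) const { return offset[i + 1] - offset[i]; }

  // position of j in i's neighbour list, or -1
  int find(int i, int j) const {
    const int* lo = nbr.data() + offset[i];
    const int* hi = nbr.data() + offset[i + 1];
    const int* it = std::lower_bound(lo, hi, j);
    return (it != hi && *it == j) ? static_cast<int>(it - lo) : -1;
  }

  bool has_edge(int i, int j) const { return find(i, j) >= 0; }

  void build_tables(double p, double q) {
    node_tab.resize(n);
    for (int i = 0; i < n; ++i) {
      int d = degree(i);
      if (d == 0) continue;
      std::vector<double> ww(w.begin() + offset[i], w.begin() + offset[i + 1]);
      node_tab[i].build(ww);
    }
    // one table per directed edge (u -> v): distribution over neighbours of v
    edge_tab.resize(offset[n]);
    for (int u = 0; u < n; ++u) {
      for (int t = offset[u]; t < offset[u + 1]; ++t) {
        int v = nbr[t];
        int dv = degree(v);
        if (dv == 0) continue;
        std::vector<double> ww(dv);
        for (int s = 0; s < dv; ++s) {
          int x = nbr[offset[v] + s];
          double base = w[offset[v] + s];
          if (x == u)
            ww[s] = base / p;          // return to previous node
          else if (has_edge(u, x))
            ww[s] = base;              // common neighbour of previous
          else
            ww[s] = base / q;          // move outward
        }
        edge_tab[t].build(ww);
      }
    }
  }
};

struct Engine {
  Layer lay[2];  // 0 = structural, 1 = functional
  std::vector<double> ps;  // P(structural layer | node), Eq. 5

  void init(const List& s_idx, const List& s_w, const List& f_idx,
            const List& f_w, const NumericVector& info_s,
            const NumericVector& info_f, double p, double q) {
    lay[0].init(s_idx, s_w);
    lay[1].init(f_idx, f_w);
    lay[0].build_tables(p, q);
    lay[1].build_tables(p, q);
    int n = lay[0].n;
    ps.resize(n);
    for (int i = 0; i < n; ++i) ps[i] = info_s[i] / (info_s[i] + info_f[i]);
  }

  std::vector<int> walk(int start, int len, Rng& rng) const {
    std::vector<int> seq;
    seq.reserve(len + 1);
    seq.push_back(start);
    int cur = start, prev = -1;
    for (int step = 0; step < len; ++step) {
      int lj = (rng.unif() < ps[cur]) ? 0 : 1;
      if (lay[lj].degree(cur) == 0) {
        lj = 1 - lj;
        if (lay[lj].degree(cur) == 0) break;  // isolated in both layers
      }
      const Layer& L = lay[lj];
      int nxt_pos = -1;
      int epos = (prev >= 0) ? L.find(prev, cur) : -1;
      if (epos >= 0)  // edge (prev, cur) exists in the chosen layer
        nxt_pos = L.edge_tab[L.offset[prev] + epos].draw(rng);
      else
        nxt_pos = L.node_tab[cur].draw(rng);
      int nxt = L.nbr[L.offset[cur] + nxt_pos];
      seq.push_back(nxt);
      prev = cur;
      cur = nxt;
    }
    return seq;
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_alias_build(NumericVector w) {
  std::vector<double> ww(w.begin(), w.end());
  AliasTable t;
  t.build(ww);
  return List::create(_["prob"] = NumericVector(t.prob.begin(), t.prob.end()),
                      _["alias"] = IntegerVector(t.alias.begin(), t.alias.end()));
}

// [[Rcpp::export]]
List cpp_alias_sample(NumericVector prob, IntegerVector alias, int n,
                      double seed) {
  AliasTable t;
  t.prob.assign(prob.begin(), prob.end());
  t.alias.assign(alias.begin(), alias.end());
  Rng rng(static_cast<uint64_t>(seed));
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = t.draw(rng);
  return List::create(_["sample"] = out, _["rng_draws"] = (double)rng.draws);
}

// [[Rcpp::export]]
List cpp_simulate_walks(List s_idx, List s_w, List f_idx, List f_w,
                        NumericVector info_s, NumericVector info_f, double p,
                        double q, int start, int walk_length, int n_walks,
                        double seed) {
  Engine eng;
  eng.init(s_idx, s_w, f_idx, f_w, info_s, info_f, p, q);
  Rng rng(static_cast<uint64_t>(seed));
  List out(n_walks);
  for (int i = 0; i < n_walks; ++i) {
    std::vector<int> sq = eng.walk(start, walk_length, rng);
    out[i] = IntegerVector(sq.begin(), sq.end());
  }
  return out;
}

// [[Rcpp::export]]
List cpp_generate_corpus(List s_idx, List s_w, List f_idx, List f_w,
                         NumericVector info_s, NumericVector info_f, double p,
                         double q, int walk_length, int walks_per_node,
                         double seed) {
  Engine eng;
  eng.init(s_idx, s_w, f_idx, f_w, info_s, info_f, p, q);
  int n = eng.lay[0].n;
  Rng rng(static_cast<uint64_t>(seed));
  List out(n * walks_per_node);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  int k = 0;
  for (int rep = 0; rep < walks_per_node; ++rep) {
    // Fisher-Yates reshuffle per repetition for corpus diversity
    for (int i = n - 1; i > 0; --i)
      std::swap(order[i], order[rng.unif_int(i + 1)]);
    for (int i = 0; i < n; ++i) {
      std::vector<int> sq = eng.walk(order[i], walk_length, rng);
      out[k++] = IntegerVector(sq.begin(), sq.end());
    }
  }
  return out;
}
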