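// Hierarchical Navigable Small World (HNSW) graph index over unit vectors.
// Distance is cosine distance (1 - dot product); rows of the input matrix
// are assumed L2-normalized by the R layer. Build and search are fully
// deterministic given the seed.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <random>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

typedef std::pair<double, int> DI; // (distance, node)

static inline double dist_to(const NumericMatrix &X, int i, const double *q, int d) {
  double s = 0.0;
  const double *xi = &X(i, 0);
  // NumericMatrix is column-major; stride between columns is nrow
  int n = X.nrow();
  for (int c = 0; c < d; ++c) s += xi[(R_xlen_t)c * n] * q[c];
  return 1.0 - s;
}

struct Graph {
  int M, Mmax0, ef_construction, max_level, entry;
  double mL;
  std::vector<int> levels;                        // level per node
  std::vector<std::vector<std::vector<int>>> nbr; // nbr[layer][node]
};

// Greedy ef-search on one layer among the first `n_active` nodes.
static std::vector<DI> search_layer(const NumericMatrix &X, const Graph &g,
                                    const double *q, int d,
                                    const std::vector<int> &entries,
                                    int ef, int layer,
                                    std::vector<int> &visited, int stamp) {
  std::priority_queue<DI, std::vector<DI>, std::greater<DI>> cand; // min-heap
  std::priority_queue<DI> top;                                     // max-heap
  for (int e : entries) {
    if (visited[e] == stamp) continue;
    visited[e] = stamp;
    double de = dist_to(X, e, q, d);
    cand.push({de, e});
    top.push({de, e});
    if ((int)top.size() > ef) top.pop();
  }
  while (!cand.empty()) {
    DI c = cand.top();
    if (c.first > top.top().first && (int)top.size() >= ef) break;
    cand.pop();
    const std::vector<int> &nb = g.nbr[layer][c.second];
    for (int u : nb) {
      if (visited[u] == stamp) continue;
      visited[u] = stamp;
      double du = dist_to(X, u, q, d);
      if ((int)top.size() < ef || du < top.top().first) {
        cand.push({du, u});
        top.push({du, u});
        if ((int)top.size() > ef) top.pop();
      }
    }
  }
  std::vector<DI> out;
  out.reserve(top.size());
  while (!top.empty()) { out.push_back(top.top()); top.pop(); }
  std::reverse(out.begin(), out.end()); // nearest first
  return out;
}

static void connect(Graph &g, int layer, int node, const std::vector<DI> &near,
                    const NumericMatrix &X, int d) {
  int M = g.M;
  int Mmax = (layer == 0) ? g.Mmax0 : g.M;
  int take = std::min((int)near.size(), M);
  std::vector<int> &mine = g.nbr[layer][node];
  for (int t = 0; t < take; ++t) {
    int u = near[t].second;
    if (u == node) continue;
    mine.push_back(u);
    std::vector<int> &theirs = g.nbr[layer][u];
    theirs.push_back(node);
    if ((int)theirs.size() > Mmax) {
      // prune to the Mmax nearest of u
      const double *qu = nullptr;
      std::vector<double> ubuf(d);
      int n = X.nrow();
      for (int c = 0; c < d; ++c) ubuf[c] = X(u, c);
      qu = ubuf.data();
      std::vector<DI> cand;
      cand.reserve(theirs.size());
      for (int w : theirs) cand.push_back({dist_to(X, w, qu, d), w});
      std::partial_sort(cand.begin(), cand.begin() + Mmax, cand.end());
      theirs.clear();
      for (int t2 = 0; t2 < Mmax; ++t2) theirs.push_back(cand[t2].second);
      (void)n;
    }
  }
}

// [[Rcpp::export]]
List hnsw_build_cpp(NumericMatrix X, int M, int ef_construction, int seed) {
  int N = X.nrow(), d = X.ncol();
  Graph g;
  g.M = M;
  g.Mmax0 = 2 * M;
  g.ef_construction = ef_construction;
  g.mL = 1.0 / std::log((double)M);
  g.levels.assign(N, 0);
  g.max_level = 0;
  g.entry = 0;
  std::mt19937 rng((unsigned)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  for (int i = 0; i < N; ++i) {
    double u = unif(rng);
    if (u < 1e-12) u = 1e-12;
    g.levels[i] = (int)std::floor(-std::log(u) * g.mL);
  }
  int top_level = *std::max_element(g.levels.begin(), g.levels.end());
  g.nbr.assign(top_level + 1, std::vector<std::vector<int>>(N));
  std::vector<int> visited(N, -1);
  std::vector<double> qbuf(d);
  for (int i = 0; i < N; ++i) {
    for (int c = 0; c < d; ++c) qbuf[c] = X(i, c);
    const double *q = qbuf.data();
    int lvl = g.levels[i];
    if (i == 0) { g.entry = 0; g.max_level = lvl; continue; }
    int ep = g.entry;
    // greedy descent through layers above the node's level
    for (int lc = g.max_level; lc > lvl; --lc) {
      bool improved = true;
      double dep = dist_to(X, ep, q, d);
      while (improved) {
        improved = false;
        for (int u : g.nbr[lc][ep]) {
          double du = dist_to(X, u, q, d);
          if (du < dep) { dep = du; ep = u; improved = true; }
        }
      }
    }
    std::vector<int> entries(1, ep);
    for (int lc = std::min(lvl, g.max_level); lc >= 0; --lc) {
      std::vector<DI> near = search_layer(X, g, q, d, entries, ef_construction,
                                          lc, visited, i * (top_level + 1) + lc);
      connect(g, lc, i, near, X, d);
      entries.clear();
      for (const DI &p : near) entries.push_back(p.second);
      if (entries.empty()) entries.push_back(ep);
    }
    if (lvl > g.max_level) { g.max_level = lvl; g.entry = i; }
  }
  // serialize: per layer, list of integer vectors (1-based)
  List layers(g.max_level + 1);
  for (int l = 0; l <= g.max_level; ++l) {
    List ln(N);
    for (int i = 0; i < N; ++i) {
      IntegerVector v(g.nbr[l][i].size());
      for (size_t t = 0; t < g.nbr[l][i].size(); ++t) v[t] = g.nbr[l][i][t] + 1;
      ln[i] = v;
    }
    layers[l] = ln;
  }
  return List::create(_["layers"] = layers,
                      _["levels"] = IntegerVector(g.levels.begin(), g.levels.end()),
                      _["entry"] = g.entry + 1,
                      _["max_level"] = g.max_level,
                      _["M"] = M,
                      _["ef_construction"] = ef_construction,
                      _["seed"] = seed);
}

// [[Rcpp::export]]
IntegerMatrix hnsw_search_cpp(NumericMatrix X, List graph, NumericMatrix Q,
                              int k, int ef_search) {
  int N = X.nrow(), d = X.ncol();
  List layers = graph["layers"];
  int max_level = as<int>(graph["max_level"]);
  int entry = as<int>(graph["entry"]) - 1;
  // deserialize adjacency once per call
  Graph g;
  g.max_level = max_level;
  g.entry = entry;
  g.nbr.assign(max_level + 1, std::vector<std::vector<int>>(N));
  for (int l = 0; l <= max_level; ++l) {
    List ln = layers[l];
    for (int i = 0; i < N; ++i) {
      IntegerVector v = ln[i];
      std::vector<int> &dst = g.nbr[l][i];
      dst.reserve(v.size());
      for (int t = 0; t < v.size(); ++t) dst.push_back(v[t] - 1);
    }
  }
  int nq = Q.nrow();
  int ef = std::max(ef_search, k);
  IntegerMatrix out(nq, k);
  std::vector<int> visited(N, -1);
  std::vector<double> qbuf(d);
  for (int qi = 0; qi < nq; ++qi) {
    for (int c = 0; c < d; ++c) qbuf[c] = Q(qi, c);
    const double *q = qbuf.data();
    int ep = entry;
    for (int lc = max_level; lc > 0; --lc) {
      bool improved = true;
      double dep = dist_to(X, ep, q, d);
      while (improved) {
        improved = false;
        for (int u : g.nbr[lc][ep]) {
          double du = dist_to(X, u, q, d);
          if (du < dep) { dep = du; ep = u; improved = true; }
        }
      }
    }
    std::vector<int> entries(1, ep);
    std::vector<DI> near = search_layer(X, g, q, d, entries, ef, 0,
                                        visited, qi + 1);
    for (int t = 0; t < k; ++t)
      out(qi, t) = (t < (int)near.size()) ? near[t].second + 1 : NA_INTEGER;
  }
  return out;
}
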