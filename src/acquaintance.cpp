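#include <Rcpp.h>
#include <vector>
#include <unordered_set>

using namespace Rcpp;

// Acquaintance small-world growth model. Node count is fixed; each
// iteration a random node either introduces two of its neighbors to each
// other (if it has >= 2 neighbors) or links itself to a random other node;
// afterwards, with probability p_d, a random node is replaced by a newcomer
// that keeps none of the old edges and receives one random link. Uses R's
// RNG so results are reproducible under set.seed().

namespace {

inline long long key(int u, int v, int n) {
  if (u > v) std::swap(u, v);
  return (long long)u * n + v;
}

struct Graph {
  int n;
  std::vector<std::vector<int>> adj;
  std::unordered_set<long long> edges;

  explicit Graph(int n_) : n(n_), adj(n_) {}

  bool has(int u, int v) const { return edges.count(key(u, v, n)) > 0; }

  void add(int u, int v) {
    if (u == v || has(u, v)) return;
    edges.insert(key(u, v, n));
    adj[u].push_back(v);
    adj[v].push_back(u);
  }

  void drop_node(int w) {
    for (int v : adj[w]) {
      edges.erase(key(w, v, n));
      std::vector<int> &a = adj[v];
      for (size_t k = 0; k < a.size(); ++k) {
        if (a[k] == w) { a[k] = a.back(); a.pop_back(); break; }
      }
    }
    adj[w].clear();
  }
};

inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

} // namespace

// [[Rcpp::export]]
IntegerMatrix acquaintance_run(int n_nodes, IntegerMatrix init_edges,
                               double p_d, double iterations) {
  Graph g(n_nodes);
  for (int r = 0; r < init_edges.nrow(); ++r)
    g.add(init_edges(r, 0), init_edges(r, 1));

  for (double it = 0; it < iterations; ++it) {
    int i = runif_int(n_nodes);
    int deg = (int)g.adj[i].size();
    if (deg >= 2) {
      int a = runif_int(deg);
      int b = runif_int(deg);
      while (b == a) b = runif_int(deg);
      g.add(g.adj[i][a], g.adj[i][b]);
    } else {
      int j = runif_int(n_nodes);
      while (j == i) j = runif_int(n_nodes);
      g.add(i, j);
    }
    if (p_d > 0 && unif_rand() < p_d) {
      int w = runif_int(n_nodes);
      g.drop_node(w);
      int x = runif_int(n_nodes);
      while (x == w) x = runif_int(n_nodes);
      g.add(w, x);
    }
  }

  IntegerMatrix out((int)g.edges.size(), 2);
  int r = 0;
  for (int u = 0; u < n_nodes; ++u) {
    for (int v : g.adj[u]) {
      if (v > u) { out(r, 0) = u; out(r, 1) = v; ++r; }
    }
  }
  return out;
}
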