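#include <Rcpp.h>
#include <vector>
#include <queue>
#include <unordered_set>
#include <cstdint>
#include <climits>
#include <functional>

using namespace Rcpp;

// Hopcroft-Karp maximum bipartite matching.
//
// n_left / n_right: part sizes; adj: adjacency of each left node as 1-based
// right indices; left_order: 1-based processing order of left nodes.  The
// matching returned is maximum; WHICH maximum matching is selected depends
// deterministically on left_order and on the adjacency order.
//
// Returns match_left (for each left node its matched right index, 0 if
// unmatched) and match_right (the reverse map).
// [[Rcpp::export(name = ".hopcroft_karp_cpp")]]
List hopcroft_karp_cpp(int n_left, int n_right, List adj, IntegerVector left_order) {
  const int INF = INT_MAX;
  std::vector<std::vector<int>> g(n_left);
  for (int u = 0; u < n_left; ++u) {
    IntegerVector nb = adj[u];
    g[u].assign(nb.begin(), nb.end());
    for (int &v : g[u]) --v;  // 0-based
  }
  std::vector<int> order(left_order.begin(), left_order.end());
  for (int &u : order) --u;

  std::vector<int> ml(n_left, -1), mr(n_right, -1), dist(n_left);

  auto bfs = [&]() -> bool {
    std::queue<int> q;
    for (int u : order) {
      if (ml[u] == -1) { dist[u] = 0; q.push(u); }
      else dist[u] = INF;
    }
    bool found = false;
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (int v : g[u]) {
        int w = mr[v];
        if (w == -1) {
          found = true;
        } else if (dist[w] == INF) {
          dist[w] = dist[u] + 1;
          q.push(w);
        }
      }
    }
    return found;
  };

  // iterative DFS along the BFS layering
  std::function<bool(int)> try_augment = [&](int u) -> bool {
    for (int v : g[u]) {
      int w = mr[v];
      if (w == -1 || (dist[w] == dist[u] + 1 && try_augment(w))) {
        ml[u] = v; mr[v] = u;
        return true;
      }
    }
    dist[u] = INF;
    return false;
  };

  while (bfs()) {
    for (int u : order)
      if (ml[u] == -1) try_augment(u);
  }

  IntegerVector match_left(n_left), match_right(n_right);
  for (int u = 0; u < n_left; ++u) match_left[u] = ml[u] + 1;
  for (int v = 0; v < n_right; ++v) match_right[v] = mr[v] + 1;
  return List::create(_["match_left"] = match_left,
                      _["match_right"] = match_right);
}

// Degree-preserving double-edge swaps on a simple digraph.
//
// Picks two edges (a,b), (c,d) uniformly and replaces them by (a,d), (c,b),
// rejecting swaps that would create a self-loop or a duplicate edge.  Every
// node keeps its exact in- and out-degree.  Uses R's RNG so results are
// reproducible under set.seed().  Gives up after max_attempts total draws.
// [[Rcpp::export(name = ".rewire_swaps_cpp")]]
List rewire_swaps_cpp(IntegerVector from, IntegerVector to, int n_nodes,
                      double swaps, double max_attempts) {
  R_xlen_t m = from.size();
  std::vector<int> f(from.begin(), from.end()), t(to.begin(), to.end());
  std::unordered_set<int64_t> present;
  present.reserve(2 * m);
  auto key = [n_nodes](int a, int b) {
    return (int64_t)(a - 1) * n_nodes + (b - 1);
  };
  for (R_xlen_t i = 0; i < m; ++i) present.insert(key(f[i], t[i]));

  double done = 0, attempts = 0;
  while (done < swaps && attempts < max_attempts) {
    attempts += 1;
    R_xlen_t i = (R_xlen_t)(unif_rand() * m);
    R_xlen_t j = (R_xlen_t)(unif_rand() * m);
    if (i == j) continue;
    int a = f[i], b = t[i], c = f[j], d = t[j];
    if (a == d || c == b) continue;                 // self-loop
    if (b == d || a == c) continue;                 // swap is a no-op / dup
    if (present.count(key(a, d)) || present.count(key(c, b))) continue;
    present.erase(key(a, b));
    present.erase(key(c, d));
    present.insert(key(a, d));
    present.insert(key(c, b));
    t[i] = d; t[j] = b;
    done += 1;
  }

  return List::create(_["from"] = IntegerVector(f.begin(), f.end()),
                      _["to"] = IntegerVector(t.begin(), t.end()),
                      _["performed"] = done);
}
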