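// Girvan-Newman community detection on an unweighted undirected graph:
// repeatedly remove the edge with maximal betweenness (recomputed after every
// removal, restricted to the affected component), track the connected-
// component partition along the removal sequence, and return the partition
// maximizing Newman-Girvan modularity on the ORIGINAL graph. Ties in
// betweenness break by canonical (input) edge order; ties in modularity keep
// the first maximum, so the result is deterministic.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Graph {
  int n, m;
  // adjacency with erasure: (neighbor, edge id) pairs, swap-removed when an
  // edge is deleted so traversal cost tracks the live edge count
  std::vector<std::vector<std::pair<int, int>>> adj;
  std::vector<int> ea, eb_; // edge endpoints
  std::vector<char> alive;

  void build(const IntegerMatrix &edges, int n_nodes) {
    n = n_nodes;
    m = edges.nrow();
    adj.assign(n, {});
    ea.resize(m);
    eb_.resize(m);
    alive.assign(m, 1);
    for (int e = 0; e < m; ++e) {
      ea[e] = edges(e, 0);
      eb_[e] = edges(e, 1);
      adj[ea[e]].push_back({eb_[e], e});
      adj[eb_[e]].push_back({ea[e], e});
    }
  }
  void erase_half(int v, int e) {
    auto &a = adj[v];
    for (size_t i = 0; i < a.size(); ++i)
      if (a[i].second == e) {
        a[i] = a.back();
        a.pop_back();
        return;
      }
  }
  void remove_edge(int e) {
    alive[e] = 0;
    erase_half(ea[e], e);
    erase_half(eb_[e], e);
  }
};

// scratch arrays for Brandes/BFS, sized n once
struct Scratch {
  std::vector<int> dist, order, qbuf, mark;
  std::vector<double> sigma, delta;
  int token = 0;
  explicit Scratch(int n)
      : dist(n), order(n), qbuf(n), mark(n, -1), sigma(n), delta(n) {}
};

// Brandes accumulation (edge betweenness) sourced at every node in `nodes`.
// Adds each ordered pair's contribution; caller halves for undirected counts.
void brandes_component(const Graph &g, const std::vector<int> &nodes,
                       std::vector<double> &ebet, Scratch &sc) {
  for (int s : nodes) {
    for (int v : nodes) {
      sc.dist[v] = -1;
      sc.sigma[v] = 0.0;
      sc.delta[v] = 0.0;
    }
    sc.dist[s] = 0;
    sc.sigma[s] = 1.0;
    int qh = 0, qt = 0;
    sc.qbuf[qt++] = s;
    int no = 0;
    while (qh < qt) {
      int v = sc.qbuf[qh++];
      sc.order[no++] = v;
      for (auto &pr : g.adj[v]) {
        int w = pr.first;
        if (sc.dist[w] < 0) {
          sc.dist[w] = sc.dist[v] + 1;
          sc.qbuf[qt++] = w;
        }
        if (sc.dist[w] == sc.dist[v] + 1) sc.sigma[w] += sc.sigma[v];
      }
    }
    for (int i = no - 1; i >= 0; --i) {
      int w = sc.order[i];
      for (auto &pr : g.adj[w]) {
        int v = pr.first;
        if (sc.dist[v] == sc.dist[w] - 1) {
          double c = sc.sigma[v] / sc.sigma[w] * (1.0 + sc.delta[w]);
          ebet[pr.second] += c;
          sc.delta[v] += c;
        }
      }
    }
  }
}

// nodes of the live component containing `start`
std::vector<int> component_of(const Graph &g, int start, Scratch &sc) {
  int token = ++sc.token;
  std::vector<int> nodes;
  int qh = 0, qt = 0;
  sc.qbuf[qt++] = start;
  sc.mark[start] = token;
  while (qh < qt) {
    int v = sc.qbuf[qh++];
    nodes.push_back(v);
    for (auto &pr : g.adj[v])
      if (sc.mark[pr.first] != token) {
        sc.mark[pr.first] = token;
        sc.qbuf[qt++] = pr.first;
      }
  }
  return nodes;
}

// Newman-Girvan modularity of partition `comp` on the original graph
double modularity(const Graph &g, const std::vector<int> &comp, int ncomp,
                  const std::vector<int> &orig_degree) {
  if (g.m == 0) return 0.0;
  std::vector<double> within(ncomp, 0.0), degsum(ncomp, 0.0);
  for (int e = 0; e < g.m; ++e)
    if (comp[g.ea[e]] == comp[g.eb_[e]]) within[comp[g.ea[e]]] += 1.0;
  for (int v = 0; v < g.n; ++v) degsum[comp[v]] += (double)orig_degree[v];
  double q = 0.0, m2 = 2.0 * g.m;
  for (int c = 0; c < ncomp; ++c) {
    double dc = degsum[c] / m2;
    q += within[c] / g.m - dc * dc;
  }
  return q;
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_edge_betweenness(IntegerMatrix edges, int n_nodes) {
  Graph g;
  g.build(edges, n_nodes);
  Scratch sc(g.n);
  std::vector<double> ebet(g.m, 0.0);
  std::vector<int> all(g.n);
  for (int v = 0; v < g.n; ++v) all[v] = v;
  brandes_component(g, all, ebet, sc);
  NumericVector out(g.m);
  for (int e = 0; e < g.m; ++e) out[e] = ebet[e] / 2.0;
  return out;
}

// [[Rcpp::export]]
List cpp_girvan_newman(IntegerMatrix edges, int n_nodes) {
  Graph g;
  g.build(edges, n_nodes);
  Scratch sc(g.n);
  std::vector<int> orig_degree(g.n);
  for (int v = 0; v < g.n; ++v) orig_degree[v] = (int)g.adj[v].size();

  // initial components
  std::vector<int> comp(g.n, -1);
  int ncomp = 0;
  for (int v = 0; v < g.n; ++v) {
    if (comp[v] >= 0) continue;
    for (int u : component_of(g, v, sc)) comp[u] = ncomp;
    ++ncomp;
  }

  std::vector<double> ebet(g.m, 0.0);
  std::vector<int> all(g.n);
  for (int v = 0; v < g.n; ++v) all[v] = v;
  brandes_component(g, all, ebet, sc);

  double best_q = modularity(g, comp, ncomp, orig_degree);
  std::vector<int> best_comp = comp;
  int best_step = 0;

  for (int step = 1; step <= g.m; ++step) {
    // edge with maximal betweenness; ties -> smallest (canonical) edge id
    int emax = -1;
    double bmax = -1.0;
    for (int e = 0; e < g.m; ++e)
      if (g.alive[e] && ebet[e] > bmax + 1e-9) {
        bmax = ebet[e];
        emax = e;
      }
    if (emax < 0) break;
    int a = g.ea[emax], b = g.eb_[emax];
    g.remove_edge(emax);
    ebet[emax] = 0.0;

    // the affected component may split at the removed edge
    std::vector<int> side_a = component_of(g, a, sc);
    bool split = true;
    for (int u : side_a)
      if (u == b) {
        split = false;
        break;
      }
    if (split) {
      std::vector<int> side_b = component_of(g, b, sc);
      for (int u : side_b) comp[u] = ncomp;
      ++ncomp;
      double q = modularity(g, comp, ncomp, orig_degree);
      if (q > best_q + 1e-12) {
        best_q = q;
        best_comp = comp;
        best_step = step;
      }
      for (int u : side_a)
        for (auto &pr : g.adj[u]) ebet[pr.second] = 0.0;
      for (int u : side_b)
        for (auto &pr : g.adj[u]) ebet[pr.second] = 0.0;
      brandes_component(g, side_a, ebet, sc);
      brandes_component(g, side_b, ebet, sc);
    } else {
      for (int u : side_a)
        for (auto &pr : g.adj[u]) ebet[pr.second] = 0.0;
      brandes_component(g, side_a, ebet, sc);
    }
    if (step % 256 == 0) Rcpp::checkUserInterrupt();
  }

  // compact component ids of the best partition
  std::vector<int> remap(ncomp, -1);
  int k = 0;
  IntegerVector membership(g.n);
  for (int v = 0; v < g.n; ++v) {
    int c = best_comp[v];
    if (remap[c] < 0) remap[c] = k++;
    membership[v] = remap[c];
  }
  return List::create(_["membership"] = membership,
                      _["modularity"] = best_q,
                      _["n_communities"] = k, _["best_step"] = best_step);
}
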