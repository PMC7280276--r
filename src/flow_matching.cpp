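#include <Rcpp.h>
#include <vector>
#include <deque>
#include <limits>
using namespace Rcpp;

// Maximum-weight bipartite matching by successive shortest paths on a
// min-cost-flow network (source -> treated -> untreated -> sink, unit
// capacities, arc cost = -weight). Augmentation stops when the cheapest
// augmenting path has non-negative cost, which yields the maximum-weight
// (not necessarily maximum-cardinality) matching. Used by full_match() via
// the classical reduction of minimum-weight edge cover to matching.

struct Arc { int to; int cap; double cost; int next; };

class MCF {
public:
  std::vector<int> head;
  std::vector<Arc> arcs;
  explicit MCF(int n) : head(n, -1) {}
  void add(int u, int v, int cap, double cost) {
    arcs.push_back({v, cap, cost, head[u]}); head[u] = (int)arcs.size() - 1;
    arcs.push_back({u, 0, -cost, head[v]}); head[v] = (int)arcs.size() - 1;
  }
};

// [[Rcpp::export(name = ".mwb_matching")]]
IntegerVector mwb_matching(int n_treated, int n_untreated,
                           IntegerVector ei, IntegerVector ej,
                           NumericVector w) {
  const int S = 0, T = n_treated + n_untreated + 1;
  const int N = T + 1;
  MCF g(N);
  for (int i = 0; i < n_treated; ++i) g.add(S, 1 + i, 1, 0.0);
  for (int j = 0; j < n_untreated; ++j) g.add(1 + n_treated + j, T, 1, 0.0);
  for (int k = 0; k < ei.size(); ++k) {
    if (w[k] < 0) continue;  // unprofitable edges can never enter the matching
    g.add(1 + ei[k], 1 + n_treated + ej[k], 1, -w[k]);
  }
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> dist(N);
  std::vector<int> pre(N);
  std::vector<char> inq(N);
  for (;;) {
    // SPFA shortest path S -> T on residual arcs (costs may be negative)
    std::fill(dist.begin(), dist.end(), INF);
    std::fill(pre.begin(), pre.end(), -1);
    std::fill(inq.begin(), inq.end(), 0);
    dist[S] = 0.0;
    std::deque<int> q{S};
    inq[S] = 1;
    while (!q.empty()) {
      int u = q.front(); q.pop_front(); inq[u] = 0;
      for (int a = g.head[u]; a != -1; a = g.arcs[a].next) {
        if (g.arcs[a].cap <= 0) continue;
        int v = g.arcs[a].to;
        double nd = dist[u] + g.arcs[a].cost;
        if (nd < dist[v] - 1e-12) {
          dist[v] = nd; pre[v] = a;
          if (!inq[v]) { inq[v] = 1; q.push_back(v); }
        }
      }
    }
    // augment while the path does not lower the total weight: this returns,
    // among maximum-weight matchings, one of maximum cardinality (ties in
    // the distances then yield finer, more balanced stratifications)
    if (!(dist[T] <= 1e-9)) break;
    for (int v = T; v != S; ) {
      int a = pre[v];
      g.arcs[a].cap -= 1;
      g.arcs[a ^ 1].cap += 1;
      v = g.arcs[a ^ 1].to;
    }
  }
  // read out matching: saturated treated->untreated arcs
  IntegerVector match(n_treated, -1);
  for (int i = 0; i < n_treated; ++i) {
    for (int a = g.head[1 + i]; a != -1; a = g.arcs[a].next) {
      int v = g.arcs[a].to;
      if (v != S && g.arcs[a].cap == 0 && (a % 2 == 0)) {
        match[i] = v - 1 - n_treated;
        break;
      }
    }
  }
  return match;
}
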