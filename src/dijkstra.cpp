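#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
using namespace Rcpp;

// Single-source Dijkstra over an undirected weighted graph.
// Nodes are 1..n; edges given once per undirected pair. Returns the distance
// from `src` to every node (R_PosInf where unreachable).
// [[Rcpp::export]]
NumericVector dijkstra_source_dist(int n, IntegerVector from, IntegerVector to,
                                   NumericVector weight, int src) {
  if (src < 1 || src > n) stop("source node out of range");
  int m = from.size();
  if (to.size() != m || weight.size() != m) stop("edge vectors differ in length");

  // CSR-style adjacency for both directions
  std::vector<int> deg(n + 1, 0);
  for (int e = 0; e < m; ++e) {
    int a = from[e], b = to[e];
    if (a < 1 || a > n || b < 1 || b > n) stop("edge endpoint out of range");
    if (weight[e] < 0) stop("edge weights must be non-negative");
    ++deg[a]; ++deg[b];
  }
  std::vector<int> start(n + 2, 0);
  for (int v = 1; v <= n; ++v) start[v + 1] = start[v] + deg[v];
  std::vector<int> adj(2 * (size_t)m);
  std::vector<double> adj_w(2 * (size_t)m);
  std::vector<int> fill(n + 1, 0);
  for (int e = 0; e < m; ++e) {
    int a = from[e], b = to[e];
    double w = weight[e];
    adj[start[a] + fill[a]] = b; adj_w[start[a] + fill[a]] = w; ++fill[a];
    adj[start[b] + fill[b]] = a; adj_w[start[b] + fill[b]] = w; ++fill[b];
  }

  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> dist(n + 1, INF);
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  dist[src] = 0.0;
  pq.push(QE(0.0, src));
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    double d = top.first; int u = top.second;
    if (d > dist[u]) continue;
    for (int i = start[u]; i < start[u + 1]; ++i) {
      int v = adj[i];
      double nd = d + adj_w[i];
      if (nd < dist[v]) {
        dist[v] = nd;
        pq.push(QE(nd, v));
      }
    }
  }

  NumericVector out(n);
  for (int v = 1; v <= n; ++v) out[v - 1] = dist[v];
  return out;
}
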