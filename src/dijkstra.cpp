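#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
using namespace Rcpp;

// Dijkstra over an explicit edge list (undirected, positive costs).
// Ties in path cost are broken deterministically: after distances settle, the
// predecessor of every node is the smallest-index neighbour achieving its
// distance, so the reconstructed path is reproducible across platforms.
// [[Rcpp::export(name = ".dijkstraPath")]]
List dijkstraPath(int nNodes, IntegerVector from, IntegerVector to,
                  NumericVector cost, int src, int dst) {
  const double INF = std::numeric_limits<double>::infinity();
  const int nE = from.size();
  // CSR adjacency (both directions)
  std::vector<int> deg(nNodes, 0);
  for (int e = 0; e < nE; ++e) { ++deg[from[e]]; ++deg[to[e]]; }
  std::vector<int> ptr(nNodes + 1, 0);
  for (int v = 0; v < nNodes; ++v) ptr[v+1] = ptr[v] + deg[v];
  std::vector<int> adj(ptr[nNodes]);
  std::vector<double> wadj(ptr[nNodes]);
  std::vector<int> fill(ptr.begin(), ptr.end() - 1);
  for (int e = 0; e < nE; ++e) {
    adj[fill[from[e]]] = to[e];   wadj[fill[from[e]]++] = cost[e];
    adj[fill[to[e]]]   = from[e]; wadj[fill[to[e]]++]   = cost[e];
  }
  std::vector<double> dist(nNodes, INF);
  std::vector<char> done(nNodes, 0);
  typedef std::pair<double,int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  dist[src] = 0.0;
  pq.push(QE(0.0, src));
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    int u = top.second;
    if (done[u]) continue;
    done[u] = 1;
    for (int p = ptr[u]; p < ptr[u+1]; ++p) {
      int v = adj[p];
      double nd = top.first + wadj[p];
      if (nd < dist[v]) { dist[v] = nd; pq.push(QE(nd, v)); }
    }
  }
  if (dist[dst] == INF)
    return List::create(_["reachable"] = false);
  // deterministic predecessors among equal-cost shortest paths
  std::vector<int> pred(nNodes, -1);
  std::vector<int> path;
  int cur = dst;
  while (cur != src) {
    int best = -1;
    for (int p = ptr[cur]; p < ptr[cur+1]; ++p) {
      int u = adj[p];
      if (dist[u] + wadj[p] == dist[cur] && (best == -1 || u < best)) best = u;
    }
    if (best == -1) return List::create(_["reachable"] = false); // numeric guard
    path.push_back(cur);
    cur = best;
  }
  path.push_back(src);
  IntegerVector out(path.size());
  for (size_t i = 0; i < path.size(); ++i)
    out[i] = path[path.size() - 1 - i] + 1; // 1-based, src .. dst
  return List::create(_["reachable"] = true, _["path"] = out,
                      _["cost"] = dist[dst]);
}

// All-pairs-free single-source distances (used for graph diagnostics).
// [[Rcpp::export(name = ".nearestVertexDist")]]
NumericVector nearestVertexDist(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double ax = A(i,0), ay = A(i,1), az = A(i,2);
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      double dx = ax - B(j,0), dy = ay - B(j,1), dz = az - B(j,2);
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
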