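#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// All-pairs weighted shortest-path statistics by repeated Dijkstra.
// Edges are 0-based endpoint indices with precomputed lengths (1/weight).
// Returns (sum of 1/d over connected ordered pairs,
//          sum of d over connected ordered pairs,
//          number of connected ordered pairs).
// The removal trajectories call this thousands of times per network, which
// is why it lives in C++ rather than going through graph objects.
// [[Rcpp::export]]
NumericVector all_pairs_distance_stats(IntegerVector from, IntegerVector to,
                                       NumericVector len, int n) {
  std::vector<std::vector<std::pair<int, double> > > adj(n);
  int m = from.size();
  for (int e = 0; e < m; ++e) {
    adj[from[e]].push_back(std::make_pair(to[e], len[e]));
    adj[to[e]].push_back(std::make_pair(from[e], len[e]));
  }
  double sum_inv = 0.0, sum_d = 0.0;
  double n_conn = 0.0;
  std::vector<double> dist(n);
  typedef std::pair<double, int> P;
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    dist[s] = 0.0;
    std::priority_queue<P, std::vector<P>, std::greater<P> > pq;
    pq.push(std::make_pair(0.0, s));
    while (!pq.empty()) {
      double d = pq.top().first;
      int u = pq.top().second;
      pq.pop();
      if (d > dist[u]) continue;
      for (size_t a = 0; a < adj[u].size(); ++a) {
        double nd = d + adj[u][a].second;
        int v = adj[u][a].first;
        if (nd < dist[v]) {
          dist[v] = nd;
          pq.push(std::make_pair(nd, v));
        }
      }
    }
    for (int t = 0; t < n; ++t) {
      if (t == s || !std::isfinite(dist[t])) continue;
      sum_inv += 1.0 / dist[t];
      sum_d += dist[t];
      n_conn += 1.0;
    }
  }
  return NumericVector::create(sum_inv, sum_d, n_conn);
}
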