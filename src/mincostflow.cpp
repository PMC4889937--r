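#include <Rcpp.h>
#include <vector>
#include <limits>

// Successive shortest paths with node potentials (Johnson reduction) on
// real-valued capacities. All input arc costs must be >= 0, so the zero
// potential is valid initially; potentials keep reduced costs non-negative
// across iterations and Dijkstra stays applicable.
//
// Determinism: Dijkstra scans nodes in index order and picks the smallest
// index among minimal tentative distances; parents are updated only on a
// strict improvement (beyond a fixed tolerance). Node indices are assigned
// by the caller in sorted name order, so equal-cost ties break
// lexicographically.

static const double INF = std::numeric_limits<double>::infinity();

// [[Rcpp::export]]
Rcpp::List mcmf_ssp(int n_nodes,
                    Rcpp::IntegerVector from,
                    Rcpp::IntegerVector to,
                    Rcpp::NumericVector capacity,
                    Rcpp::NumericVector cost,
                    int source, int sink,
                    double flow_eps) {
  const int m = from.size();
  // residual arcs: 2*m entries, arc 2k forward, 2k+1 backward
  std::vector<int> head(2 * m), nxt(2 * m), first(n_nodes, -1);
  std::vector<double> rcap(2 * m), rcost(2 * m);
  for (int k = 0; k < m; ++k) {
    int u = from[k], v = to[k];
    head[2 * k] = v; rcap[2 * k] = capacity[k]; rcost[2 * k] = cost[k];
    nxt[2 * k] = first[u]; first[u] = 2 * k;
    head[2 * k + 1] = u; rcap[2 * k + 1] = 0.0; rcost[2 * k + 1] = -cost[k];
    nxt[2 * k + 1] = first[v]; first[v] = 2 * k + 1;
  }

  std::vector<double> pot(n_nodes, 0.0), dist(n_nodes);
  std::vector<int> par_arc(n_nodes);
  std::vector<bool> done(n_nodes);
  double total_flow = 0.0, total_cost = 0.0;
  const double tie_tol = 1e-15;
  // each augmentation saturates at least one arc; generous guard against
  // float pathologies
  const long max_iter = 4L * (m + 1L) + 64L;
  long iter = 0;

  while (iter++ < max_iter) {
    std::fill(dist.begin(), dist.end(), INF);
    std::fill(done.begin(), done.end(), false);
    std::fill(par_arc.begin(), par_arc.end(), -1);
    dist[source] = 0.0;
    for (int scan = 0; scan < n_nodes; ++scan) {
      int u = -1; double best = INF;
      for (int v = 0; v < n_nodes; ++v)
        if (!done[v] && dist[v] < best) { best = dist[v]; u = v; }
      if (u < 0) break;
      done[u] = true;
      for (int a = first[u]; a != -1; a = nxt[a]) {
        if (rcap[a] <= flow_eps) continue;
        int v = head[a];
        double rc = rcost[a] + pot[u] - pot[v];
        if (rc < 0.0) rc = 0.0; // float guard: reduced costs are >= 0 in exact arithmetic
        double nd = dist[u] + rc;
        if (nd < dist[v] - tie_tol) { dist[v] = nd; par_arc[v] = a; }
      }
    }
    if (!std::isfinite(dist[sink])) break; // no augmenting path

    double dt = dist[sink];
    for (int v = 0; v < n_nodes; ++v)
      if (std::isfinite(dist[v])) pot[v] += std::min(dist[v], dt);

    // bottleneck
    double aug = INF;
    for (int v = sink; v != source;) {
      int a = par_arc[v];
      if (aug > rcap[a]) aug = rcap[a];
      v = head[a ^ 1];
    }
    if (!(aug > flow_eps)) break;
    for (int v = sink; v != source;) {
      int a = par_arc[v];
      rcap[a] -= aug;
      rcap[a ^ 1] += aug;
      total_cost += aug * rcost[a];
      v = head[a ^ 1];
    }
    total_flow += aug;
  }

  Rcpp::NumericVector flow(m);
  for (int k = 0; k < m; ++k) flow[k] = rcap[2 * k + 1]; // backward residual = flow sent
  return Rcpp::List::create(Rcpp::Named("flow") = flow,
                            Rcpp::Named("total_flow") = total_flow,
                            Rcpp::Named("total_cost") = total_cost);
}
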