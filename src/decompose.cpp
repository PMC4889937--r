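#include <Rcpp.h>
#include <vector>
#include <limits>

// Widest-path-first flow decomposition: repeatedly extract the s->t path
// whose bottleneck (minimum remaining arc flow) is largest, subtract it,
// and stop when no path with bottleneck > eps remains. Deterministic:
// nodes are scanned in index order and predecessors updated only on a
// strict improvement, so ties resolve to the smallest node index (the
// caller assigns indices in lexicographic name order).

// [[Rcpp::export]]
Rcpp::List decompose_widest(int n_nodes,
                            Rcpp::IntegerVector from,
                            Rcpp::IntegerVector to,
                            Rcpp::NumericVector flow,
                            int source, int sink,
                            double eps) {
  const int m = from.size();
  std::vector<double> rem(flow.begin(), flow.end());
  std::vector<int> head(m), nxt(m), first(n_nodes, -1);
  for (int k = 0; k < m; ++k) {
    head[k] = to[k];
    nxt[k] = first[from[k]];
    first[from[k]] = k;
  }
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> width(n_nodes);
  std::vector<int> par(n_nodes);
  std::vector<bool> done(n_nodes);
  Rcpp::List paths;
  const long max_paths = 4L * m + 64L;

  for (long it = 0; it < max_paths; ++it) {
    std::fill(width.begin(), width.end(), 0.0);
    std::fill(done.begin(), done.end(), false);
    std::fill(par.begin(), par.end(), -1);
    width[source] = INF;
    for (int scan = 0; scan < n_nodes; ++scan) {
      int u = -1;
      double best = 0.0;
      for (int v = 0; v < n_nodes; ++v)
        if (!done[v] && width[v] > best) { best = width[v]; u = v; }
      if (u < 0) break;
      done[u] = true;
      for (int k = first[u]; k != -1; k = nxt[k]) {
        if (rem[k] <= eps) continue;
        double w = std::min(width[u], rem[k]);
        if (w > width[head[k]] + 1e-15) { width[head[k]] = w; par[head[k]] = k; }
      }
    }
    if (!(width[sink] > eps)) break;
    // walk back, subtract, emit
    std::vector<int> arcs_on_path;
    for (int v = sink; v != source;) {
      arcs_on_path.push_back(par[v]);
      v = from[par[v]];
    }
    double b = width[sink];
    std::vector<int> nodes_on_path;
    nodes_on_path.push_back(source);
    for (auto it2 = arcs_on_path.rbegin(); it2 != arcs_on_path.rend(); ++it2) {
      rem[*it2] -= b;
      nodes_on_path.push_back(head[*it2]);
    }
    paths.push_back(Rcpp::List::create(
        Rcpp::Named("nodes") = Rcpp::IntegerVector(nodes_on_path.begin(),
                                                   nodes_on_path.end()),
        Rcpp::Named("flow") = b));
  }
  return paths;
}
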