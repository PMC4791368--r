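#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// All-pairs shortest paths by Floyd-Warshall on a dense length matrix.
// len(i,j): edge length (> 0), R_PosInf where no edge. Diagonal is forced to 0.
// [[Rcpp::export]]
NumericMatrix fw_distances(NumericMatrix len) {
  int n = len.nrow();
  if (len.ncol() != n) stop("length matrix must be square");
  NumericMatrix d = clone(len);
  for (int i = 0; i < n; ++i) d(i, i) = 0.0;
  for (int k = 0; k < n; ++k) {
    for (int i = 0; i < n; ++i) {
      double dik = d(i, k);
      if (dik == R_PosInf) continue;
      for (int j = 0; j < n; ++j) {
        double alt = dik + d(k, j);
        if (alt < d(i, j)) d(i, j) = alt;
      }
    }
  }
  return d;
}

// Per-node weighted clustering, geometric-mean (Onnela) variant.
// w: symmetric max-normalized weights in [0,1], zero diagonal.
// C_i = (1 / (k_i (k_i - 1))) * sum_{j != h} (w_ij w_ih w_jh)^(1/3)
// [[Rcpp::export]]
NumericVector onnela_clustering(NumericMatrix w) {
  int n = w.nrow();
  NumericMatrix cw(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      cw(i, j) = std::cbrt(w(i, j));
  NumericVector cc(n);
  for (int i = 0; i < n; ++i) {
    std::vector<int> nb;
    for (int j = 0; j < n; ++j)
      if (j != i && w(i, j) > 0) nb.push_back(j);
    int k = (int) nb.size();
    if (k < 2) { cc[i] = 0.0; continue; }
    double s = 0.0;
    for (int a = 0; a < k; ++a)
      for (int b = 0; b < k; ++b) {
        if (a == b) continue;
        s += cw(i, nb[a]) * cw(i, nb[b]) * cw(nb[a], nb[b]);
      }
    cc[i] = s / ((double) k * (k - 1));
  }
  return cc;
}

static double subgraph_efficiency(const NumericMatrix &w,
                                  const std::vector<int> &nodes) {
  int m = (int) nodes.size();
  std::vector<double> d(m * m);
  for (int a = 0; a < m; ++a)
    for (int b = 0; b < m; ++b) {
      if (a == b) { d[a * m + b] = 0.0; continue; }
      double wij = w(nodes[a], nodes[b]);
      d[a * m + b] = (wij > 0) ? 1.0 / wij : R_PosInf;
    }
  for (int k = 0; k < m; ++k)
    for (int a = 0; a < m; ++a) {
      double dak = d[a * m + k];
      if (dak == R_PosInf) continue;
      for (int b = 0; b < m; ++b) {
        double alt = dak + d[k * m + b];
        if (alt < d[a * m + b]) d[a * m + b] = alt;
      }
    }
  double s = 0.0;
  for (int a = 0; a < m; ++a)
    for (int b = 0; b < m; ++b) {
      if (a == b) continue;
      double dd = d[a * m + b];
      if (dd != R_PosInf) s += 1.0 / dd;
    }
  return s / ((double) m * (m - 1));
}

// Mean local efficiency: for each node, global efficiency of the subgraph
// induced by its neighbors (node excluded); nodes with < 2 neighbors give 0.
// w: symmetric max-normalized weights, zero diagonal.
// [[Rcpp::export]]
double local_efficiency_mean(NumericMatrix w) {
  int n = w.nrow();
  double total = 0.0;
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    nb.clear();
    for (int j = 0; j < n; ++j)
      if (j != i && w(i, j) > 0) nb.push_back(j);
    if ((int) nb.size() < 2) continue;
    total += subgraph_efficiency(w, nb);
  }
  return total / n;
}

// Degree-preserving rewiring by repeated double-edge swaps.
// ei, ej: 0-based endpoints of the E undirected edges; weights stay attached
// to their edge slot in R. Swaps creating self-loops or multi-edges are
// rejected. Uses R's RNG (seedable from R with set.seed()).
// [[Rcpp::export]]
List double_edge_swap(IntegerVector ei, IntegerVector ej, int n_nodes,
                      int n_attempts) {
  int E = ei.size();
  IntegerVector ri = clone(ei), rj = clone(ej);
  std::vector<char> adj((size_t) n_nodes * n_nodes, 0);
  for (int e = 0; e < E; ++e) {
    adj[(size_t) ri[e] * n_nodes + rj[e]] = 1;
    adj[(size_t) rj[e] * n_nodes + ri[e]] = 1;
  }
  int accepted = 0;
  for (int t = 0; t < n_attempts; ++t) {
    int e1 = (int) std::floor(unif_rand() * E);
    int e2 = (int) std::floor(unif_rand() * E);
    if (e1 == e2) continue;
    int a = ri[e1], b = rj[e1], c = ri[e2], d = rj[e2];
    if (unif_rand() < 0.5) std::swap(c, d);
    // propose (a,b),(c,d) -> (a,d),(c,b)
    if (a == d || c == b) continue;
    if (adj[(size_t) a * n_nodes + d] || adj[(size_t) c * n_nodes + b])
      continue;
    adj[(size_t) a * n_nodes + b] = adj[(size_t) b * n_nodes + a] = 0;
    adj[(size_t) c * n_nodes + d] = adj[(size_t) d * n_nodes + c] = 0;
    adj[(size_t) a * n_nodes + d] = adj[(size_t) d * n_nodes + a] = 1;
    adj[(size_t) c * n_nodes + b] = adj[(size_t) b * n_nodes + c] = 1;
    ri[e1] = a; rj[e1] = d;
    ri[e2] = c; rj[e2] = b;
    ++accepted;
  }
  return List::create(_["i"] = ri, _["j"] = rj, _["accepted"] = accepted);
}
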