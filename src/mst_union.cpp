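#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive enumeration of all labelled spanning trees of the complete
// graph on n nodes via Pruefer sequences (n^(n-2) trees; n <= 8 so at most
// 8^6 = 262144). Returns the union of all minimum-weight trees and the
// minimum weight. Weight ties are compared with a small tolerance.

// [[Rcpp::export]]
List cpp_mst_union(NumericMatrix d) {
  const int n = d.nrow();
  LogicalMatrix uni(n, n);
  if (n == 2) {
    uni(0, 1) = uni(1, 0) = true;
    return List::create(_["union"] = uni, _["weight"] = d(0, 1));
  }
  const int m = n - 2;
  std::vector<int> pruefer(m, 0);
  std::vector<int> degree(n), edge_u(n - 1), edge_v(n - 1);
  double best = R_PosInf;
  const double eps = 1e-9;

  for (;;) {
    // decode: repeatedly join the smallest remaining leaf to pruefer[i]
    for (int i = 0; i < n; ++i) degree[i] = 1;
    for (int i = 0; i < m; ++i) degree[pruefer[i]]++;
    double w = 0.0;
    for (int i = 0; i < m; ++i) {
      int leaf = 0;
      while (degree[leaf] != 1) ++leaf;
      int v = pruefer[i];
      edge_u[i] = leaf; edge_v[i] = v;
      w += d(leaf, v);
      degree[leaf] = 0;
      degree[v]--;
    }
    int a = -1, b = -1;
    for (int i = 0; i < n; ++i)
      if (degree[i] == 1) { if (a < 0) a = i; else b = i; }
    edge_u[m] = a; edge_v[m] = b;
    w += d(a, b);

    if (w < best - eps) {
      best = w;
      std::fill(uni.begin(), uni.end(), false);
    }
    if (w <= best + eps) {
      for (int i = 0; i < n - 1; ++i) {
        uni(edge_u[i], edge_v[i]) = true;
        uni(edge_v[i], edge_u[i]) = true;
      }
    }
    // next Pruefer sequence (odometer increment)
    int k = m - 1;
    while (k >= 0 && pruefer[k] == n - 1) { pruefer[k] = 0; --k; }
    if (k < 0) break;
    pruefer[k]++;
  }
  return List::create(_["union"] = uni, _["weight"] = best);
}
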