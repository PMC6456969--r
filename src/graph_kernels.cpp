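#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>

using namespace Rcpp;

// CSR convention: ptr has n+1 0-based offsets into nbr/wt; nbr holds 0-based
// neighbour ids; every undirected edge appears in both adjacency lists.

// [[Rcpp::export]]
NumericVector cpp_sssp(IntegerVector ptr, IntegerVector nbr, NumericVector wt,
                       int source) {
  const int n = ptr.size() - 1;
  const double inf = std::numeric_limits<double>::infinity();
  std::vector<double> dist(n, inf);
  typedef std::pair<double, int> QN;
  std::priority_queue<QN, std::vector<QN>, std::greater<QN> > pq;
  dist[source] = 0.0;
  pq.push(QN(0.0, source));
  const int *p = ptr.begin();
  const int *nb = nbr.begin();
  const double *w = wt.begin();
  while (!pq.empty()) {
    QN top = pq.top();
    pq.pop();
    int u = top.second;
    double du = top.first;
    if (du > dist[u]) continue; // stale entry
    for (int k = p[u]; k < p[u + 1]; ++k) {
      int v = nb[k];
      double nd = du + w[k];
      if (nd < dist[v]) {
        dist[v] = nd;
        pq.push(QN(nd, v));
      }
    }
  }
  return NumericVector(dist.begin(), dist.end());
}

// Distance table with one ROW per source: returns length(sources) x n matrix.
// [[Rcpp::export]]
NumericMatrix cpp_sssp_multi(IntegerVector ptr, IntegerVector nbr,
                             NumericVector wt, IntegerVector sources) {
  const int n = ptr.size() - 1;
  const int l = sources.size();
  NumericMatrix out(l, n);
  const double inf = std::numeric_limits<double>::infinity();
  const int *p = ptr.begin();
  const int *nb = nbr.begin();
  const double *w = wt.begin();
  std::vector<double> dist(n);
  typedef std::pair<double, int> QN;
  for (int s = 0; s < l; ++s) {
    std::fill(dist.begin(), dist.end(), inf);
    std::priority_queue<QN, std::vector<QN>, std::greater<QN> > pq;
    dist[sources[s]] = 0.0;
    pq.push(QN(0.0, sources[s]));
    while (!pq.empty()) {
      QN top = pq.top();
      pq.pop();
      int u = top.second;
      double du = top.first;
      if (du > dist[u]) continue;
      for (int k = p[u]; k < p[u + 1]; ++k) {
        int v = nb[k];
        double nd = du + w[k];
        if (nd < dist[v]) {
          dist[v] = nd;
          pq.push(QN(nd, v));
        }
      }
    }
    for (int v = 0; v < n; ++v) out(s, v) = dist[v];
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Hop-count distance table for uniform-weight graphs (BFS per source);
// callers scale by the common edge weight. Returns length(sources) x n.
// [[Rcpp::export]]
NumericMatrix cpp_bfs_multi(IntegerVector ptr, IntegerVector nbr,
                            IntegerVector sources) {
  const int n = ptr.size() - 1;
  const int l = sources.size();
  NumericMatrix out(l, n);
  const double inf = std::numeric_limits<double>::infinity();
  const int *p = ptr.begin();
  const int *nb = nbr.begin();
  std::vector<int> dist(n), queue(n);
  for (int s = 0; s < l; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    int head = 0, tail = 0;
    dist[sources[s]] = 0;
    queue[tail++] = sources[s];
    while (head < tail) {
      int u = queue[head++];
      int du = dist[u];
      for (int k = p[u]; k < p[u + 1]; ++k) {
        int v = nb[k];
        if (dist[v] < 0) {
          dist[v] = du + 1;
          queue[tail++] = v;
        }
      }
    }
    for (int v = 0; v < n; ++v) {
      out(s, v) = dist[v] < 0 ? inf : (double)dist[v];
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Connected component labels (0-based), iterative BFS.
// [[Rcpp::export]]
IntegerVector cpp_components(IntegerVector ptr, IntegerVector nbr) {
  const int n = ptr.size() - 1;
  IntegerVector comp(n, -1);
  const int *p = ptr.begin();
  const int *nb = nbr.begin();
  std::vector<int> stack;
  int label = 0;
  for (int s = 0; s < n; ++s) {
    if (comp[s] >= 0) continue;
    comp[s] = label;
    stack.push_back(s);
    while (!stack.empty()) {
      int u = stack.back();
      stack.pop_back();
      for (int k = p[u]; k < p[u + 1]; ++k) {
        int v = nb[k];
        if (comp[v] < 0) {
          comp[v] = label;
          stack.push_back(v);
        }
      }
    }
    ++label;
  }
  return comp;
}

// min over the first l_use pivot rows of D[p,i] + D[p,j] for each pair.
// D is l x n (column-major: D[,v] is contiguous).
// [[Rcpp::export]]
NumericVector cpp_query_pairs(NumericMatrix D, IntegerVector iv,
                              IntegerVector jv, int l_use) {
  const int l = D.nrow();
  const int m = iv.size();
  NumericVector out(m);
  const double *d = D.begin();
  for (int q = 0; q < m; ++q) {
    int i = iv[q], j = jv[q];
    if (i == j) {
      out[q] = 0.0;
      continue;
    }
    const double *ci = d + (size_t)i * l;
    const double *cj = d + (size_t)j * l;
    double best = std::numeric_limits<double>::infinity();
    for (int pcol = 0; pcol < l_use; ++pcol) {
      double s = ci[pcol] + cj[pcol];
      if (s < best) best = s;
    }
    out[q] = best;
  }
  return out;
}

// Full symmetric approximate-distance matrix for a node subset.
// [[Rcpp::export]]
NumericMatrix cpp_query_submatrix(NumericMatrix D, IntegerVector idx,
                                  int l_use) {
  const int l = D.nrow();
  const int m = idx.size();
  NumericMatrix out(m, m);
  const double *d = D.begin();
  for (int a = 0; a < m; ++a) {
    const double *ca = d + (size_t)idx[a] * l;
    for (int b = a + 1; b < m; ++b) {
      const double *cb = d + (size_t)idx[b] * l;
      double best = std::numeric_limits<double>::infinity();
      for (int pcol = 0; pcol < l_use; ++pcol) {
        double s = ca[pcol] + cb[pcol];
        if (s < best) best = s;
      }
      out(a, b) = best;
      out(b, a) = best;
    }
  }
  return out;
}
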