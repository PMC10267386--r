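#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Reverse Cuthill-McKee reordering of a rectangular matrix's bipartite
// graph followed by CSR assembly on the renumbered axes.  Must stay
// order-identical to the pure-R reference in R/rcm.R: traversal starts at
// the unvisited node of minimum degree (lowest index first), neighbours
// enter the queue in increasing (degree, index), exhausted components
// restart at the next minimum-degree node, and the final ordering is
// reversed.
//
// it0 holds the 0-based row-major linear positions of the non-zeros
// (position = row * n + column), already sorted, with v alongside; the
// returned row_perm/col_perm are 1-based old-to-new positions, indices
// are 0-based CSR column indices on the renumbered axes.
// [[Rcpp::export]]
List casagm_reorder_csr(IntegerVector it0, NumericVector v, int m, int n) {
  const int N = m + n;
  const R_xlen_t nnz = v.size();

  std::vector<int> deg(N, 0);
  for (R_xlen_t k = 0; k < nnz; ++k) {
    const int idx = it0[k];
    ++deg[idx / n];
    ++deg[m + idx % n];
  }

  std::vector<int> ptr(N + 1, 0);
  for (int u = 0; u < N; ++u) ptr[u + 1] = ptr[u] + deg[u];

  // start order: counting sort of nodes by (degree, index)
  std::vector<int> start(N);
  {
    int maxdeg = 0;
    for (int u = 0; u < N; ++u) maxdeg = std::max(maxdeg, deg[u]);
    std::vector<int> cnt(maxdeg + 2, 0);
    for (int u = 0; u < N; ++u) ++cnt[deg[u] + 1];
    for (int d = 1; d <= maxdeg + 1; ++d) cnt[d] += cnt[d - 1];
    for (int u = 0; u < N; ++u) start[cnt[deg[u]]++] = u;
  }

  // neighbour lists in (degree, index) order without per-node sorts:
  // visiting nodes in `start` order and appending each to its neighbours'
  // lists leaves every list sorted by the visitor's rank.  The unsorted
  // adjacency is scoped so its memory is released before the traversal.
  std::vector<int> adj(2 * (size_t)nnz);
  {
    std::vector<int> raw(2 * (size_t)nnz);
    std::vector<int> fill(ptr.begin(), ptr.end() - 1);
    for (R_xlen_t k = 0; k < nnz; ++k) {
      const int idx = it0[k];
      const int u = idx / n, w = m + idx % n;
      raw[fill[u]++] = w;
      raw[fill[w]++] = u;
    }
    std::copy(ptr.begin(), ptr.end() - 1, fill.begin());
    for (int q = 0; q < N; ++q) {
      const int u = start[q];
      for (int e = ptr[u]; e < ptr[u + 1]; ++e) adj[fill[raw[e]]++] = u;
    }
  }

  std::vector<int> order;
  order.reserve(N);
  std::vector<char> visited(N, 0);
  std::vector<int> queue(N);
  int sp = 0;
  while ((int)order.size() < N) {
    while (visited[start[sp]]) ++sp;
    int s = start[sp];
    visited[s] = 1;
    int qh = 0, qt = 0;
    queue[qt++] = s;
    while (qh < qt) {
      const int c = queue[qh++];
      order.push_back(c);
      for (int e = ptr[c]; e < ptr[c + 1]; ++e) {
        const int w = adj[e];
        if (!visited[w]) {
          visited[w] = 1;
          queue[qt++] = w;
        }
      }
    }
  }
  std::reverse(order.begin(), order.end());

  IntegerVector row_perm(m), col_perm(n);
  {
    int r = 0, c = 0;
    for (int k = 0; k < N; ++k) {
      const int node = order[k];
      if (node < m)
        row_perm[node] = ++r;
      else
        col_perm[node - m] = ++c;
    }
  }

  // CSR on the renumbered axes: stable counting sort by new column, then
  // by new row (row-major order)
  std::vector<int> ni(nnz), nj(nnz);
  for (R_xlen_t k = 0; k < nnz; ++k) {
    const int idx = it0[k];
    ni[k] = row_perm[idx / n];
    nj[k] = col_perm[idx % n];
  }
  std::vector<int> bycol(nnz);
  {
    std::vector<int> cnt(n + 1, 0);
    for (R_xlen_t k = 0; k < nnz; ++k) ++cnt[nj[k]];
    for (int c = 1; c <= n; ++c) cnt[c] += cnt[c - 1];
    for (R_xlen_t k = nnz - 1; k >= 0; --k) bycol[--cnt[nj[k]]] = k;
  }

  IntegerVector indptr(m + 1), indices(nnz);
  NumericVector values(nnz);
  for (R_xlen_t k = 0; k < nnz; ++k) ++indptr[ni[k]];
  for (int r = 1; r <= m; ++r) indptr[r] += indptr[r - 1];
  {
    // second, stable counting pass writes the row-major stream directly
    std::vector<R_xlen_t> fill(m);
    for (int r = 0; r < m; ++r) fill[r] = indptr[r];
    for (R_xlen_t q = 0; q < nnz; ++q) {
      const int k = bycol[q];
      const R_xlen_t dst = fill[ni[k] - 1]++;
      indices[dst] = nj[k] - 1;
      values[dst] = v[k];
    }
  }

  return List::create(_["row_perm"] = row_perm, _["col_perm"] = col_perm,
                      _["indptr"] = indptr, _["indices"] = indices,
                      _["values"] = values);
}

// Inverse of the pipeline: expand the renumbered CSR payload into the
// dense matrix in its original row/column order.  indptr/indices are the
// stored (0-based) CSR arrays on the renumbered axes; row_perm/col_perm
// are the stored 1-based old-to-new positions.  Bounds and pointer
// monotonicity are validated before any write.
// [[Rcpp::export]]
NumericMatrix casagm_invert_csr(IntegerVector indptr, IntegerVector indices,
                                NumericVector values, IntegerVector row_perm,
                                IntegerVector col_perm, int m, int n) {
  const R_xlen_t nnz = values.size();
  if (indptr.size() != m + 1 || indptr[0] != 0 || indptr[m] != nnz ||
      indices.size() != nnz)
    stop("CSR pointer array malformed");
  for (int r = 0; r < m; ++r)
    if (indptr[r + 1] < indptr[r]) stop("CSR pointer array malformed");

  // invert the permutations: new position -> original index (0-based)
  std::vector<int> orow(m), ocol(n);
  for (int r = 0; r < m; ++r) {
    const int p = row_perm[r];
    if (p < 1 || p > m) stop("row permutation out of range");
    orow[p - 1] = r;
  }
  for (int c = 0; c < n; ++c) {
    const int p = col_perm[c];
    if (p < 1 || p > n) stop("column permutation out of range");
    ocol[p - 1] = c;
  }

  NumericMatrix A(m, n);
  for (int r = 0; r < m; ++r) {
    const int i0 = orow[r];
    for (int e = indptr[r]; e < indptr[r + 1]; ++e) {
      const int c = indices[e];
      if (c < 0 || c >= n) stop("CSR index out of bounds");
      A[(R_xlen_t)ocol[c] * m + i0] = values[e];
    }
  }
  return A;
}
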