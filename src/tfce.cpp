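#include <Rcpp.h>
using namespace Rcpp;

// Union-find with path compression + union by size.
static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int>& parent, std::vector<int>& size,
                     int a, int b) {
  a = uf_find(parent, a);
  b = uf_find(parent, b);
  if (a == b) return;
  if (size[a] < size[b]) std::swap(a, b);
  parent[b] = a;
  size[a] += size[b];
}

// TFCE transform of a non-negative map on a 4-connected grid:
// out[p] = sum over heights h = dh, 2*dh, ..., h <= m[p] of
//          extent(cluster of {m >= h} containing p)^E * h^H * dh.
// Clusters are tracked incrementally from the highest level down with a
// union-find, so the cost is O(npix * nsteps + npix log npix).
// [[Rcpp::export]]
NumericMatrix tfce_nonneg(NumericMatrix m, double dh, double E, double H,
                          int nsteps) {
  int nr = m.nrow(), nc = m.ncol(), n = nr * nc;
  NumericMatrix out(nr, nc);
  if (dh <= 0 || nsteps < 1) return out;
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return m[a] > m[b]; });
  std::vector<int> parent(n), size(n, 0);
  std::vector<char> active(n, 0);
  for (int i = 0; i < n; ++i) parent[i] = i;
  int next_add = 0;
  std::vector<int> active_list;
  active_list.reserve(n);
  for (int step = nsteps; step >= 1; --step) {
    double h = step * dh;
    while (next_add < n && m[order[next_add]] >= h) {
      int p = order[next_add];
      active[p] = 1;
      size[p] = 1;
      active_list.push_back(p);
      int r = p % nr, c = p / nr;
      if (r > 0 && active[p - 1]) uf_union(parent, size, p, p - 1);
      if (r < nr - 1 && active[p + 1]) uf_union(parent, size, p, p + 1);
      if (c > 0 && active[p - nr]) uf_union(parent, size, p, p - nr);
      if (c < nc - 1 && active[p + nr]) uf_union(parent, size, p, p + nr);
      ++next_add;
    }
    if (active_list.empty()) continue;
    double hh = std::pow(h, H) * dh;
    for (size_t k = 0; k < active_list.size(); ++k) {
      int p = active_list[k];
      int root = uf_find(parent, p);
      out[p] += std::pow((double)size[root], E) * hh;
    }
  }
  return out;
}
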