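#include <Rcpp.h>
using namespace Rcpp;

// Disjoint-set forest with union by size and path halving.
// Regions carry Int(R): the largest edge weight accepted into R's
// merge history (0 for singletons).

static inline int uf_find(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// Sorted-edge region merging.
//
// Edges (ei, ej, ew) must arrive sorted ascending by (weight, i, j);
// vertex ids are 0-based. Merge rule for the current edge of weight w
// joining roots a != b:
//   IRM(a, b) = w  (minimum connecting weight, by ascending order)
//   DT(a, b)  = min(Int(a) + k/|a|, Int(b) + k/|b|)
//   merge iff IRM <= DT
// After the main pass, a cleanup stage guarantees every surviving
// region has at least min_size pixels (unless the whole image is
// smaller). It re-walks the sorted edges twice: first merging pairs
// where BOTH sides are undersized (agglomerating fragments into
// homogeneous groups along the cheapest edges, without letting a large
// region swallow long chains of fragments), then attaching any
// remaining undersized region to its lowest-connecting-weight
// neighbor. Int of a merged region becomes max(Int(a), Int(b), w).
//
// Returns 1-based root labels, one per vertex.
// [[Rcpp::export(name = ".uf_segment")]]
IntegerVector uf_segment(int n_vertices,
                         IntegerVector ei,
                         IntegerVector ej,
                         NumericVector ew,
                         double k_scale,
                         int min_size) {
  const int m = ei.size();
  std::vector<int> parent(n_vertices), size(n_vertices, 1);
  std::vector<double> internal(n_vertices, 0.0);
  for (int v = 0; v < n_vertices; ++v) parent[v] = v;

  for (int e = 0; e < m; ++e) {
    int a = uf_find(parent, ei[e]);
    int b = uf_find(parent, ej[e]);
    if (a == b) continue;
    double w = ew[e];
    double dt = std::min(internal[a] + k_scale / size[a],
                         internal[b] + k_scale / size[b]);
    if (w <= dt) {
      if (size[a] < size[b]) std::swap(a, b);
      parent[b] = a;
      size[a] += size[b];
      internal[a] = std::max(w, std::max(internal[a], internal[b]));
    }
  }

  if (min_size > 1) {
    for (int e = 0; e < m; ++e) {
      int a = uf_find(parent, ei[e]);
      int b = uf_find(parent, ej[e]);
      if (a == b) continue;
      if (size[a] < min_size && size[b] < min_size) {
        if (size[a] < size[b]) std::swap(a, b);
        parent[b] = a;
        size[a] += size[b];
        internal[a] = std::max(ew[e], std::max(internal[a], internal[b]));
      }
    }
    for (int e = 0; e < m; ++e) {
      int a = uf_find(parent, ei[e]);
      int b = uf_find(parent, ej[e]);
      if (a == b) continue;
      if (size[a] < min_size || size[b] < min_size) {
        if (size[a] < size[b]) std::swap(a, b);
        parent[b] = a;
        size[a] += size[b];
        internal[a] = std::max(ew[e], std::max(internal[a], internal[b]));
      }
    }
  }

  IntegerVector labels(n_vertices);
  for (int v = 0; v < n_vertices; ++v) labels[v] = uf_find(parent, v) + 1;
  return labels;
}
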