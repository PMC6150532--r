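#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// union-find with path compression
static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// Two-pass connected-component labelling of a logical matrix.
// eight = true uses 8-connectivity (edges + diagonals), else 4.
// Returns an integer matrix: 0 = background, components labelled 1..n
// in raster order.
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(const LogicalMatrix& mask, bool eight = true) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);
  int next = 1;

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      int best = 0;
      // neighbours already visited in column-major raster order:
      // (r-1, c), (r, c-1), and diagonals (r-1, c-1), (r+1, c-1)
      int cand[4][2] = {{r - 1, c}, {r - 1, c - 1}, {r, c - 1}, {r + 1, c - 1}};
      int nnb = eight ? 4 : 0;
      int nb4[2][2] = {{r - 1, c}, {r, c - 1}};
      for (int i = 0; i < (eight ? nnb : 2); ++i) {
        int rr = eight ? cand[i][0] : nb4[i][0];
        int cc = eight ? cand[i][1] : nb4[i][1];
        if (rr < 0 || rr >= nr || cc < 0) continue;
        int l = lab(rr, cc);
        if (l > 0) {
          if (best == 0) best = l;
          else uf_union(parent, best, l);
        }
      }
      if (best == 0) {
        parent.push_back(next);
        lab(r, c) = next++;
      } else {
        lab(r, c) = uf_find(parent, best);
      }
    }
  }

  // relabel compactly in raster order of first occurrence
  std::vector<int> remap(next, 0);
  int out = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l == 0) continue;
      int root = uf_find(parent, l);
      if (remap[root] == 0) remap[root] = ++out;
      lab(r, c) = remap[root];
    }
  }
  return lab;
}
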