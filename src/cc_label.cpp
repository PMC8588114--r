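#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Two-pass connected-component labelling with union-find.
// 8-connectivity: components change if this is altered, so it is fixed here
// rather than delegated to an image library with unspecified connectivity.

static int uf_find(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// [[Rcpp::export]]
IntegerMatrix cc_label_8(LogicalMatrix m) {
  int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.push_back(0); // label 0 = background, self-parented

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!m(i, j)) continue;
      // previously scanned 8-neighbours in column-major order:
      // (i-1, j), (i-1, j-1), (i, j-1), (i+1, j-1)
      int neigh[4][2] = {{i - 1, j}, {i - 1, j - 1}, {i, j - 1}, {i + 1, j - 1}};
      int best = 0;
      for (int k = 0; k < 4; ++k) {
        int r = neigh[k][0], c = neigh[k][1];
        if (r < 0 || r >= nr || c < 0) continue;
        int l = lab(r, c);
        if (l > 0) {
          if (best == 0) best = l;
          else uf_union(parent, best, l);
        }
      }
      if (best == 0) {
        int newlab = (int)parent.size();
        parent.push_back(newlab);
        lab(i, j) = newlab;
      } else {
        lab(i, j) = best;
      }
    }
  }

  // second pass: resolve labels to root, compress to 1..n
  std::vector<int> remap(parent.size(), 0);
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int l = lab(i, j);
      if (l == 0) continue;
      int root = uf_find(parent, l);
      if (remap[root] == 0) remap[root] = ++next;
      lab(i, j) = remap[root];
    }
  }
  return lab;
}
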