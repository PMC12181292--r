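#include <Rcpp.h>
using namespace Rcpp;

// Union-find with path halving.
static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// Label connected foreground components of a logical matrix.
// Labels are assigned 1..k in raster-scan (row-major) discovery order.
// connectivity: 4 or 8.
// [[Rcpp::export]]
IntegerMatrix cc_label(LogicalMatrix x, int connectivity) {
  const int H = x.nrow(), W = x.ncol();
  std::vector<int> parent(static_cast<size_t>(H) * W);

  // First pass (row-major): union each foreground pixel with already-visited
  // neighbours (left, up, and for 8-connectivity the two upper diagonals).
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      const int idx = r * W + c;
      parent[idx] = idx;
      if (!x(r, c) || x(r, c) == NA_LOGICAL) continue;
      if (c > 0 && x(r, c - 1) == TRUE) uf_union(parent, idx, idx - 1);
      if (r > 0 && x(r - 1, c) == TRUE) uf_union(parent, idx, idx - W);
      if (connectivity == 8) {
        if (r > 0 && c > 0 && x(r - 1, c - 1) == TRUE)
          uf_union(parent, idx, idx - W - 1);
        if (r > 0 && c < W - 1 && x(r - 1, c + 1) == TRUE)
          uf_union(parent, idx, idx - W + 1);
      }
    }
  }

  // Second pass: roots appear in raster order because uf_union keeps the
  // smallest row-major index as root; number them in order of first occurrence.
  IntegerMatrix out(H, W);
  std::unordered_map<int, int> lab;
  int next = 0;
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (!x(r, c) || x(r, c) == NA_LOGICAL) { out(r, c) = 0; continue; }
      const int root = uf_find(parent, r * W + c);
      auto it = lab.find(root);
      if (it == lab.end()) { lab.emplace(root, ++next); out(r, c) = next; }
      else out(r, c) = it->second;
    }
  }
  return out;
}
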