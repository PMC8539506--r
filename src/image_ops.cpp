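#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Two-pass union-find connected-component labelling of a binary image.
// Labels are compacted to 1..n_components in order of first (column-major)
// appearance, matching R's matrix storage order.

namespace {
int find_root(std::vector<int> &par, int x) {
  while (par[x] != x) { par[x] = par[par[x]]; x = par[x]; }
  return x;
}
void unite(std::vector<int> &par, int a, int b) {
  a = find_root(par, a); b = find_root(par, b);
  if (a != b) par[std::max(a, b)] = std::min(a, b);
}
} // namespace

// [[Rcpp::export]]
IntegerMatrix cc_label_cpp(const LogicalMatrix &img, int connectivity) {
  const int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> par(1, 0); // provisional labels; index 0 unused
  int next = 1;

  const bool diag = (connectivity == 8);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!img(r, c)) continue;
      int best = 0;
      // previously visited neighbours in column-major order
      int cand[4][2] = {{r - 1, c}, {r, c - 1}, {r - 1, c - 1}, {r + 1, c - 1}};
      int ncand = diag ? 4 : 2;
      for (int k = 0; k < ncand; ++k) {
        int rr = cand[k][0], cc2 = cand[k][1];
        if (rr < 0 || rr >= nr || cc2 < 0) continue;
        int l = lab(rr, cc2);
        if (l > 0) {
          if (best == 0) best = l;
          else unite(par, best, l);
        }
      }
      if (best == 0) { par.push_back(next); best = next++; }
      lab(r, c) = best;
    }
  }

  // compact labels in order of first appearance
  std::vector<int> remap(next, 0);
  int out = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l == 0) continue;
      int root = find_root(par, l);
      if (remap[root] == 0) remap[root] = ++out;
      lab(r, c) = remap[root];
    }
  lab.attr("n_components") = out;
  return lab;
}

// Per-label pixel counts and exposed-edge perimeter.  The perimeter
// convention is the number of unit pixel edges separating a labelled pixel
// from background or from a differently labelled pixel (4-neighbourhood),
// i.e. the length of the rasterised boundary polygon.

// [[Rcpp::export]]
List region_stats_cpp(const IntegerMatrix &lab, int n_labels) {
  const int nr = lab.nrow(), nc = lab.ncol();
  NumericVector area(n_labels), perim(n_labels), rsum(n_labels), csum(n_labels);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l == 0) continue;
      int i = l - 1;
      area[i] += 1.0; rsum[i] += r + 1; csum[i] += c + 1;
      if (r == 0 || lab(r - 1, c) != l) perim[i] += 1.0;
      if (r == nr - 1 || lab(r + 1, c) != l) perim[i] += 1.0;
      if (c == 0 || lab(r, c - 1) != l) perim[i] += 1.0;
      if (c == nc - 1 || lab(r, c + 1) != l) perim[i] += 1.0;
    }
  }
  for (int i = 0; i < n_labels; ++i) {
    if (area[i] > 0) { rsum[i] /= area[i]; csum[i] /= area[i]; }
  }
  return List::create(_["area_px"] = area, _["perimeter_px"] = perim,
                      _["centroid_row"] = rsum, _["centroid_col"] = csum);
}
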