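#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling on a binary mask by iterative flood fill.
// connectivity is 4 or 8; labels are assigned in raster-scan order of the
// first pixel encountered, so the labeling is deterministic.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int k = 0; k < nnb; ++k) {
          int r2 = rr + dr8[k], c2 = cc + dc8[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Fill interior holes of a binary mask: background is flood-filled
// 4-connected from the image border; any background pixel not reached is
// enclosed by foreground and becomes foreground.
// [[Rcpp::export]]
LogicalMatrix fill_holes_cpp(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix outside(nr, nc);
  std::vector<int> stack;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; c += (nc > 1 ? nc - 1 : 1)) {
      if (!mask(r, c) && !outside(r, c)) { outside(r, c) = true; stack.push_back(r + c * nr); }
      if (nc == 1) break;
    }
  }
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; r += (nr > 1 ? nr - 1 : 1)) {
      if (!mask(r, c) && !outside(r, c)) { outside(r, c) = true; stack.push_back(r + c * nr); }
      if (nr == 1) break;
    }
  }
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  while (!stack.empty()) {
    int idx = stack.back();
    stack.pop_back();
    int rr = idx % nr, cc = idx / nr;
    for (int k = 0; k < 4; ++k) {
      int r2 = rr + dr[k], c2 = cc + dc[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (!mask(r2, c2) && !outside(r2, c2)) {
        outside(r2, c2) = true;
        stack.push_back(r2 + c2 * nr);
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = mask(r, c) || !outside(r, c);
  return out;
}
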