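#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labelling of a binary mask by breadth-first flood
// fill. connectivity must be 4 or 8. Labels are 1..k in scan order of the
// first pixel encountered; background is 0.
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(const LogicalMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");

  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = (connectivity == 8) ? 8 : 4;

  std::vector<int> queue(nr * nc);
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      int head = 0, tail = 0;
      queue[tail++] = r + c * nr;
      lab(r, c) = next;
      while (head < tail) {
        const int idx = queue[head++];
        const int cr = idx % nr, cc = idx / nr;
        for (int k = 0; k < nnb; ++k) {
          const int r2 = cr + dr8[k], c2 = cc + dc8[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            queue[tail++] = r2 + c2 * nr;
          }
        }
      }
    }
  }
  return lab;
}

// Fill enclosed holes: background (0) regions not 4-connected to the raster
// border become foreground. The foreground itself is untouched, so the
// result is always a superset of the input.
// [[Rcpp::export(name = ".fill_holes_cpp")]]
LogicalMatrix fill_holes_cpp(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix reached(nr, nc);  // background reachable from the border
  std::vector<int> queue(nr * nc);
  int head = 0, tail = 0;

  auto push = [&](int r, int c) {
    if (!mask(r, c) && !reached(r, c)) {
      reached(r, c) = true;
      queue[tail++] = r + c * nr;
    }
  };
  for (int r = 0; r < nr; ++r) { push(r, 0); push(r, nc - 1); }
  for (int c = 0; c < nc; ++c) { push(0, c); push(nr - 1, c); }

  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  while (head < tail) {
    const int idx = queue[head++];
    const int cr = idx % nr, cc = idx / nr;
    for (int k = 0; k < 4; ++k) {
      const int r2 = cr + dr[k], c2 = cc + dc[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      push(r2, c2);
    }
  }

  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = mask(r, c) || !reached(r, c);
  return out;
}
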