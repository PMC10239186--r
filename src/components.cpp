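#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a logical mask by flood fill.
// connectivity: 4 or 8. Labels are dense from 1 in raster-scan discovery order.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(const LogicalMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int n_off = (connectivity == 8) ? 8 : 4;
  const int di[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int k = 0; k < n_off; ++k) {
          int qi = pi + di[k], qj = pj + dj[k];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (mask(qi, qj) && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(qi + qj * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Fill interior holes: background (FALSE) pixels not 4-connected to the image
// border become foreground. 4-connectivity for background is the dual of
// 8-connectivity for objects.
// [[Rcpp::export(name = ".fill_holes")]]
LogicalMatrix fill_holes(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix out(nr, nc);
  std::vector<char> reach((size_t) nr * nc, 0);
  std::vector<int> stack;
  const int di[4] = {-1, 1, 0, 0};
  const int dj[4] = {0, 0, -1, 1};
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      bool border = (i == 0 || i == nr - 1 || j == 0 || j == nc - 1);
      if (border && !mask(i, j) && !reach[i + (size_t) j * nr]) {
        reach[i + (size_t) j * nr] = 1;
        stack.push_back(i + j * nr);
        while (!stack.empty()) {
          int p = stack.back();
          stack.pop_back();
          int pi = p % nr, pj = p / nr;
          for (int k = 0; k < 4; ++k) {
            int qi = pi + di[k], qj = pj + dj[k];
            if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
            size_t q = qi + (size_t) qj * nr;
            if (!mask(qi, qj) && !reach[q]) {
              reach[q] = 1;
              stack.push_back(qi + qj * nr);
            }
          }
        }
      }
    }
  }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = mask(i, j) || !reach[i + (size_t) j * nr];
  return out;
}
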