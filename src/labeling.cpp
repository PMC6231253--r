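#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labelling by iterative flood fill (stack-based, no
// recursion). 2D: connectivity 4 or 8. 3D: connectivity 6 or 26. Labels are
// assigned in column-major scan order starting at 1; background stays 0.

// [[Rcpp::export]]
IntegerMatrix cpp_label2d(LogicalMatrix img, int connectivity) {
  const int ny = img.nrow(), nx = img.ncol();
  static const int dy8[8] = {-1,-1,-1, 0, 0, 1, 1, 1};
  static const int dx8[8] = {-1, 0, 1,-1, 1,-1, 0, 1};
  static const int dy4[4] = {-1, 0, 0, 1};
  static const int dx4[4] = { 0,-1, 1, 0};
  const int *dy = (connectivity == 8) ? dy8 : dy4;
  const int *dx = (connectivity == 8) ? dx8 : dx4;
  const int nn = connectivity;
  IntegerMatrix lab(ny, nx);
  std::vector<int> stack;
  int next = 0;
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      if (img(y, x) && lab(y, x) == 0) {
        ++next;
        lab(y, x) = next;
        stack.clear();
        stack.push_back(y + x * ny);
        while (!stack.empty()) {
          const int idx = stack.back(); stack.pop_back();
          const int cy = idx % ny, cx = idx / ny;
          for (int k = 0; k < nn; ++k) {
            const int yy = cy + dy[k], xx = cx + dx[k];
            if (yy >= 0 && yy < ny && xx >= 0 && xx < nx &&
                img(yy, xx) && lab(yy, xx) == 0) {
              lab(yy, xx) = next;
              stack.push_back(yy + xx * ny);
            }
          }
        }
      }
    }
  }
  lab.attr("nlabels") = next;
  return lab;
}

// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector vol, IntegerVector dims, int connectivity) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  // neighbour offsets
  std::vector<int> oi, oj, ok;
  for (int di = -1; di <= 1; ++di)
    for (int dj = -1; dj <= 1; ++dj)
      for (int dk = -1; dk <= 1; ++dk) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        const int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (connectivity == 6 && manh != 1) continue;
        oi.push_back(di); oj.push_back(dj); ok.push_back(dk);
      }
  const int nn = (int)oi.size();
  IntegerVector lab(n);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t p = 0; p < n; ++p) {
    if (vol[p] && lab[p] == 0) {
      ++next;
      lab[p] = next;
      stack.clear();
      stack.push_back(p);
      while (!stack.empty()) {
        const R_xlen_t q = stack.back(); stack.pop_back();
        const int i = (int)(q % d1);
        const int j = (int)((q / d1) % d2);
        const int k = (int)(q / ((R_xlen_t)d1 * d2));
        for (int m = 0; m < nn; ++m) {
          const int ii = i + oi[m], jj = j + oj[m], kk = k + ok[m];
          if (ii >= 0 && ii < d1 && jj >= 0 && jj < d2 && kk >= 0 && kk < d3) {
            const R_xlen_t qq = ii + (R_xlen_t)d1 * (jj + (R_xlen_t)d2 * kk);
            if (vol[qq] && lab[qq] == 0) {
              lab[qq] = next;
              stack.push_back(qq);
            }
          }
        }
      }
    }
  }
  lab.attr("dim") = dims;
  lab.attr("nlabels") = next;
  return lab;
}

// Component voxel counts for a labelled volume/matrix.
// [[Rcpp::export]]
NumericVector cpp_label_sizes(IntegerVector lab, int nlabels) {
  NumericVector sz(nlabels);
  const R_xlen_t n = lab.size();
  for (R_xlen_t p = 0; p < n; ++p) {
    const int l = lab[p];
    if (l > 0) sz[l - 1] += 1.0;
  }
  return sz;
}
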