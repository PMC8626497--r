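#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 26-connected component labeling of a 3D logical/integer array.
// Breadth-first search over foreground voxels; labels are assigned in
// first-encounter (column-major scan) order, contiguous from 1.
// [[Rcpp::export(name = ".label3d_cpp")]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> queue;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    queue.clear();
    queue.push_back(s);
    while (!queue.empty()) {
      R_xlen_t v = queue.back();
      queue.pop_back();
      int z = (int)(v % nz);
      int y = (int)((v / nz) % ny);
      int x = (int)(v / ((R_xlen_t)nz * ny));
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = x + dx;
        if (xx < 0 || xx >= nx) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          for (int dz = -1; dz <= 1; ++dz) {
            int zz = z + dz;
            if (zz < 0 || zz >= nz) continue;
            R_xlen_t w = (R_xlen_t)zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
            if (mask[w] && !lab[w]) {
              lab[w] = next;
              queue.push_back(w);
            }
          }
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
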