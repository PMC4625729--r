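#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 6-connected component labelling of a 3-D logical array (column-major),
// iterative BFS so deep components cannot overflow the C stack.
// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> queue;
  queue.reserve(1024);
  int next_label = 0;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || lab[start]) continue;
    ++next_label;
    lab[start] = next_label;
    queue.clear();
    queue.push_back(start);
    while (!queue.empty()) {
      R_xlen_t v = queue.back();
      queue.pop_back();
      int z = (int)(v / sz), rem = (int)(v % sz);
      int y = rem / nx, x = rem % nx;
      const R_xlen_t nb[6] = {v - sx, v + sx, v - sy, v + sy, v - sz, v + sz};
      const bool ok[6] = {x > 0, x < nx - 1, y > 0, y < ny - 1,
                          z > 0, z < nz - 1};
      for (int k = 0; k < 6; ++k) {
        if (ok[k] && mask[nb[k]] && !lab[nb[k]]) {
          lab[nb[k]] = next_label;
          queue.push_back(nb[k]);
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Binary dilation/erosion with an arbitrary offset set (rows of `offsets`
// are integer voxel displacements). Out-of-bounds neighbours count as
// background, the usual zero-padding convention.
// [[Rcpp::export(name = ".morph_3d")]]
LogicalVector morph_3d(LogicalVector mask, IntegerVector dim,
                       IntegerMatrix offsets, bool dilate) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  const int m = offsets.nrow();
  LogicalVector out(n);
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        R_xlen_t v = x + (R_xlen_t)y * nx + (R_xlen_t)z * sz;
        bool acc = !dilate;  // AND identity for erode, OR identity for dilate
        for (int k = 0; k < m; ++k) {
          int xx = x + offsets(k, 0), yy = y + offsets(k, 1),
              zz = z + offsets(k, 2);
          bool val = false;
          if (xx >= 0 && xx < nx && yy >= 0 && yy < ny && zz >= 0 && zz < nz)
            val = mask[xx + (R_xlen_t)yy * nx + (R_xlen_t)zz * sz];
          if (dilate) {
            if (val) { acc = true; break; }
          } else {
            if (!val) { acc = false; break; }
          }
        }
        out[v] = acc;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}
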