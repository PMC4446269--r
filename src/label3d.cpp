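#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labeling by breadth-first search.
// mask: logical/integer vector of length nz*ny*nx in (z,y,x) column-major
// order; connectivity 6 (faces), 18 (faces+edges) or 26 (all neighbours).
// [[Rcpp::export]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dims,
                          int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  // neighbour offsets in (dz, dy, dx)
  std::vector<int> dz, dy, dx;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int nonzero = (a != 0) + (b != 0) + (c != 0);
        if (nonzero == 0) continue;
        if (connectivity == 6 && nonzero > 1) continue;
        if (connectivity == 18 && nonzero > 2) continue;
        dz.push_back(a); dy.push_back(b); dx.push_back(c);
      }
  const int nn = (int)dz.size();

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> queue;
  int next_label = 0;

  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++next_label;
    labels[i] = next_label;
    queue.clear();
    queue.push_back(i);
    while (!queue.empty()) {
      R_xlen_t cur = queue.back();
      queue.pop_back();
      int cz = (int)(cur % nz);
      int cy = (int)((cur / nz) % ny);
      int cx = (int)(cur / ((R_xlen_t)nz * ny));
      for (int k = 0; k < nn; ++k) {
        int z = cz + dz[k], y = cy + dy[k], x = cx + dx[k];
        if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx) continue;
        R_xlen_t j = (R_xlen_t)x * nz * ny + (R_xlen_t)y * nz + z;
        if (mask[j] && labels[j] == 0) {
          labels[j] = next_label;
          queue.push_back(j);
        }
      }
    }
  }
  labels.attr("n_labels") = next_label;
  return labels;
}
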