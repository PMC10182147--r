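#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// 3D connected-component labelling over a logical mask stored in R's
// column-major order with dim = (nz, ny, nx).  Breadth-first search with
// 6- or 26-connectivity; labels are 1..k in discovery order, background 0.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int connectivity = 6) {
  if (dim.size() != 3) stop("dim must have length 3");
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dim");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");

  IntegerVector labels(n, 0);
  std::vector<int> dz, dy, dx;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manhattan = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manhattan != 1) continue;
        dz.push_back(a); dy.push_back(b); dx.push_back(c);
      }
  const size_t nn = dz.size();

  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    labels[start] = ++next;
    q.push(start);
    while (!q.empty()) {
      R_xlen_t i = q.front(); q.pop();
      int z = (int)(i % nz);
      int y = (int)((i / nz) % ny);
      int x = (int)(i / ((R_xlen_t)nz * ny));
      for (size_t k = 0; k < nn; ++k) {
        int z2 = z + dz[k], y2 = y + dy[k], x2 = x + dx[k];
        if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
          continue;
        R_xlen_t j = (R_xlen_t)x2 * nz * ny + (R_xlen_t)y2 * nz + z2;
        if (mask[j] && labels[j] == 0) {
          labels[j] = next;
          q.push(j);
        }
      }
    }
  }
  labels.attr("dim") = dim;
  return labels;
}
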