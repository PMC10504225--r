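#include <Rcpp.h>
using namespace Rcpp;

// Resolve 2x2 in-plane checkerboard configurations (material voxels
// touching only along a lattice edge), which would pinch the boundary
// surface. The first diagonal voxel of each configuration is carved;
// carving is monotone, so the iteration always terminates with a
// checkerboard-free (manifold-surface) mask.
// [[Rcpp::export]]
List cpp_repair_pinches(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  LogicalVector out = clone(mask);
  auto at = [&](int i, int j, int k) -> int {
    return out[(R_xlen_t)k * nxy + (R_xlen_t)j * nx + i];
  };
  auto set = [&](int i, int j, int k, int v) {
    out[(R_xlen_t)k * nxy + (R_xlen_t)j * nx + i] = v;
  };
  long changed = 0;
  bool again = true;
  int pass = 0;
  while (again && pass < 64) {
    again = false;
    ++pass;
    // axis pair (d1, d2): offsets within the plane of the two axes
    const int pairs[3][2] = {{0, 1}, {0, 2}, {1, 2}};
    for (int p = 0; p < 3; ++p) {
      int d1 = pairs[p][0], d2 = pairs[p][1];
      int s1[3] = {0, 0, 0}, s2[3] = {0, 0, 0};
      s1[d1] = 1;
      s2[d2] = 1;
      int ni = nx - s1[0] - s2[0];
      int nj = ny - s1[1] - s2[1];
      int nk = nz - s1[2] - s2[2];
      for (int k = 0; k < nk; ++k)
        for (int j = 0; j < nj; ++j)
          for (int i = 0; i < ni; ++i) {
            int a = at(i, j, k);
            int b = at(i + s1[0] + s2[0], j + s1[1] + s2[1],
                       k + s1[2] + s2[2]);
            int c = at(i + s1[0], j + s1[1], k + s1[2]);
            int d = at(i + s2[0], j + s2[1], k + s2[2]);
            if (a && b && !c && !d) {
              set(i, j, k, 0);
              ++changed;
              again = true;
            } else if (!a && !b && c && d) {
              set(i + s1[0], j + s1[1], k + s1[2], 0);
              ++changed;
              again = true;
            }
          }
    }
  }
  return List::create(_["mask"] = out, _["changed"] = (double)changed);
}
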