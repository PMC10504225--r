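#include <Rcpp.h>
#include <vector>
#include <array>
#include <cstdlib>
#include <limits>
using namespace Rcpp;

// Exact squared Euclidean distance transform of a 3D binary grid
// (Felzenszwalb & Huttenlocher lower-envelope algorithm, applied
// separably along x, y, z). Distances are in voxel units.

static const double INF = std::numeric_limits<double>::max() / 4.0;

// 1D squared distance transform of sampled function f, length n, with
// per-axis weight w: d(q) = min_v w*(q-v)^2 + f(v).
static void dt1d(const double* f, double* d, int n, int* v, double* z,
                 double w) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + w * q * q) - (f[v[k]] + w * (double)v[k] * v[k])) /
               (2.0 * w * (q - v[k]));
    while (s <= z[k]) {
      --k;
      s = ((f[q] + w * q * q) - (f[v[k]] + w * (double)v[k] * v[k])) /
          (2.0 * w * (q - v[k]));
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = w * (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Weighted squared EDT to the nearest TRUE voxel: distance^2 =
// wx*dx^2 + wy*dy^2 + wz*dz^2 in voxel units (w = c(1,1,1) gives the
// ordinary Euclidean transform; anisotropic weights realise
// ellipsoidal structuring elements). mask is a logical array with
// dims dim (length 3, column-major as in R).
// [[Rcpp::export]]
NumericVector cpp_sqedt(LogicalVector mask, IntegerVector dim,
                        NumericVector w) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  double* d = REAL(out);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = mask[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), dd(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; ++i) f[i] = d[base + i];
      dt1d(f.data(), dd.data(), nx, v.data(), z.data(), w[0]);
      for (int i = 0; i < nx; ++i) d[base + i] = dd[i];
    }
  // along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = d[base + (R_xlen_t)j * nx];
      dt1d(f.data(), dd.data(), ny, v.data(), z.data(), w[1]);
      for (int j = 0; j < ny; ++j) d[base + (R_xlen_t)j * nx] = dd[j];
    }
  // along z
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = d[base + (R_xlen_t)k * nxy];
      dt1d(f.data(), dd.data(), nz, v.data(), z.data(), w[2]);
      for (int k = 0; k < nz; ++k) d[base + (R_xlen_t)k * nxy] = dd[k];
    }
  return out;
}

// Connected-component labelling of a 3D logical array.
// connectivity: 6 or 26. Labels are 1..n, background 0; attribute "n"
// carries the component count, attribute "sizes" the voxel counts.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);

  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back({dx, dy, dz});
      }

  R_xlen_t nxy = (R_xlen_t)nx * ny;
  std::vector<R_xlen_t> queue;
  std::vector<int> sizes;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    int sz = 0;
    queue.clear();
    queue.push_back(s);
    lab[s] = next;
    while (!queue.empty()) {
      R_xlen_t cur = queue.back();
      queue.pop_back();
      ++sz;
      int k = (int)(cur / nxy);
      R_xlen_t rem = cur - (R_xlen_t)k * nxy;
      int j = (int)(rem / nx);
      int i = (int)(rem - (R_xlen_t)j * nx);
      for (const auto& o : offs) {
        int ii = i + o[0], jj = j + o[1], kk = k + o[2];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        R_xlen_t q = (R_xlen_t)kk * nxy + (R_xlen_t)jj * nx + ii;
        if (mask[q] && lab[q] == 0) {
          lab[q] = next;
          queue.push_back(q);
        }
      }
    }
    sizes.push_back(sz);
  }
  lab.attr("n") = next;
  lab.attr("sizes") = wrap(sizes);
  lab.attr("dim") = dim;
  return lab;
}
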