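#include <Rcpp.h>
#include <unordered_map>
#include <functional>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Watertight boundary surface of a 3D binary grid: every face between a
// material voxel and background (voxels outside the grid count as
// background) is emitted as two triangles with outward orientation.
// Vertices are voxel-corner coordinates in voxel units: corner c lies at
// index c - 0.5 relative to voxel centres at 0,1,2,... (0-based).

// To stay manifold at diagonal voxel contacts, a lattice corner is not
// a single shared vertex: the 8 voxels around the corner are grouped
// into face-connected clusters and each cluster receives its own
// vertex copy. Sheets that touch only along a lattice edge or corner
// then remain topologically separate (edge- and vertex-pinch free).

// [[Rcpp::export]]
List cpp_voxel_surface(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  std::unordered_map<int64_t, int> vid;
  std::vector<double> vx, vy, vz;
  std::vector<int> t0, t1, t2;
  int64_t cx = nx + 1, cy = ny + 1;

  auto at = [&](int i, int j, int k) -> bool {
    if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz)
      return false;
    return mask[(R_xlen_t)k * nxy + (R_xlen_t)j * nx + i];
  };

  // cluster id (0..7) of the owner voxel among the face-connected
  // material voxels in the 2x2x2 block behind corner (i,j,k)
  auto corner_cluster = [&](int i, int j, int k, int oi, int oj,
                            int ok) -> int {
    bool m[8];
    for (int b = 0; b < 8; ++b)
      m[b] = at(i - 1 + (b & 1), j - 1 + ((b >> 1) & 1),
                k - 1 + ((b >> 2) & 1));
    int parent[8];
    for (int b = 0; b < 8; ++b) parent[b] = b;
    std::function<int(int)> find = [&](int a) {
      while (parent[a] != a) a = parent[a] = parent[parent[a]];
      return a;
    };
    for (int b = 0; b < 8; ++b) {
      if (!m[b]) continue;
      for (int d = 0; d < 3; ++d) {
        int nb = b ^ (1 << d);
        if (nb > b && m[nb]) {
          int ra = find(b), rb = find(nb);
          if (ra != rb) parent[rb] = ra;
        }
      }
    }
    int ob = (oi - (i - 1)) + 2 * (oj - (j - 1)) + 4 * (ok - (k - 1));
    return find(ob);
  };

  auto vertex = [&](int i, int j, int k, int oi, int oj, int ok) -> int {
    int cl = corner_cluster(i, j, k, oi, oj, ok);
    int64_t key = (((int64_t)k * cy + j) * cx + i) * 8 + cl;
    auto it = vid.find(key);
    if (it != vid.end()) return it->second;
    int id = (int)vx.size();
    vid.emplace(key, id);
    vx.push_back((double)i);
    vy.push_back((double)j);
    vz.push_back((double)k);
    return id;
  };
  auto quad = [&](int a, int b, int c, int d) {
    // triangles (a,b,c) and (a,c,d)
    t0.push_back(a); t1.push_back(b); t2.push_back(c);
    t0.push_back(a); t1.push_back(c); t2.push_back(d);
  };

  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (!at(i, j, k)) continue;
        // +x face at plane i+1, outward normal (1,0,0)
        if (!at(i + 1, j, k))
          quad(vertex(i + 1, j, k, i, j, k),
               vertex(i + 1, j + 1, k, i, j, k),
               vertex(i + 1, j + 1, k + 1, i, j, k),
               vertex(i + 1, j, k + 1, i, j, k));
        // -x face at plane i, outward normal (-1,0,0)
        if (!at(i - 1, j, k))
          quad(vertex(i, j, k, i, j, k),
               vertex(i, j, k + 1, i, j, k),
               vertex(i, j + 1, k + 1, i, j, k),
               vertex(i, j + 1, k, i, j, k));
        // +y face, outward (0,1,0)
        if (!at(i, j + 1, k))
          quad(vertex(i, j + 1, k, i, j, k),
               vertex(i, j + 1, k + 1, i, j, k),
               vertex(i + 1, j + 1, k + 1, i, j, k),
               vertex(i + 1, j + 1, k, i, j, k));
        // -y face, outward (0,-1,0)
        if (!at(i, j - 1, k))
          quad(vertex(i, j, k, i, j, k),
               vertex(i + 1, j, k, i, j, k),
               vertex(i + 1, j, k + 1, i, j, k),
               vertex(i, j, k + 1, i, j, k));
        // +z face, outward (0,0,1)
        if (!at(i, j, k + 1))
          quad(vertex(i, j, k + 1, i, j, k),
               vertex(i + 1, j, k + 1, i, j, k),
               vertex(i + 1, j + 1, k + 1, i, j, k),
               vertex(i, j + 1, k + 1, i, j, k));
        // -z face, outward (0,0,-1)
        if (!at(i, j, k - 1))
          quad(vertex(i, j, k, i, j, k),
               vertex(i, j + 1, k, i, j, k),
               vertex(i + 1, j + 1, k, i, j, k),
               vertex(i + 1, j, k, i, j, k));
      }

  int nv = (int)vx.size();
  R_xlen_t nt = (R_xlen_t)t0.size();
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = vx[i];
    V(i, 1) = vy[i];
    V(i, 2) = vz[i];
  }
  IntegerMatrix F(nt, 3);
  for (R_xlen_t i = 0; i < nt; ++i) {
    F(i, 0) = t0[i] + 1;  // 1-based for R
    F(i, 1) = t1[i] + 1;
    F(i, 2) = t2[i] + 1;
  }
  return List::create(_["vertices"] = V, _["triangles"] = F);
}

// Edge-manifold diagnostics for an oriented triangle mesh.
// A closed, consistently oriented 2-manifold has every directed edge
// exactly once and its reverse exactly once.
// [[Rcpp::export]]
List cpp_mesh_status(IntegerMatrix F, int nv) {
  std::unordered_map<int64_t, int> cnt;
  R_xlen_t nt = F.nrow();
  for (R_xlen_t t = 0; t < nt; ++t) {
    int v[3] = {F(t, 0) - 1, F(t, 1) - 1, F(t, 2) - 1};
    for (int e = 0; e < 3; ++e) {
      int a = v[e], b = v[(e + 1) % 3];
      cnt[(int64_t)a * nv + b] += 1;
    }
  }
  R_xlen_t boundary = 0, nonmanifold = 0;
  for (const auto& kv : cnt) {
    int a = (int)(kv.first / nv), b = (int)(kv.first % nv);
    if (kv.second > 1) ++nonmanifold;
    auto rev = cnt.find((int64_t)b * nv + a);
    if (rev == cnt.end()) ++boundary;
  }
  return List::create(_["boundary_edges"] = (double)boundary,
                      _["nonmanifold_edges"] = (double)nonmanifold);
}

// Signed volume of an oriented triangle mesh by the divergence theorem
// (sum of signed tetrahedra against the origin). Computed relative to
// the mesh centroid for numerical stability under large translations.
// [[Rcpp::export]]
double cpp_mesh_volume(NumericMatrix V, IntegerMatrix F) {
  R_xlen_t nt = F.nrow();
  int nv = V.nrow();
  double c0 = 0, c1 = 0, c2 = 0;
  for (int i = 0; i < nv; ++i) {
    c0 += V(i, 0); c1 += V(i, 1); c2 += V(i, 2);
  }
  if (nv > 0) { c0 /= nv; c1 /= nv; c2 /= nv; }
  long double vol = 0.0;
  for (R_xlen_t t = 0; t < nt; ++t) {
    int a = F(t, 0) - 1, b = F(t, 1) - 1, c = F(t, 2) - 1;
    double ax = V(a, 0) - c0, ay = V(a, 1) - c1, az = V(a, 2) - c2;
    double bx = V(b, 0) - c0, by = V(b, 1) - c1, bz = V(b, 2) - c2;
    double cx = V(c, 0) - c0, cy = V(c, 1) - c1, cz = V(c, 2) - c2;
    vol += (long double)(ax * (by * cz - bz * cy) -
                         ay * (bx * cz - bz * cx) +
                         az * (bx * cy - by * cx));
  }
  return (double)(vol / 6.0L);
}
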