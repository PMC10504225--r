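#include <Rcpp.h>
#include <vector>
#include <array>
#include <queue>
#include <set>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Quadric-error-metric edge-collapse decimation (Garland & Heckbert
// style) for closed, consistently oriented triangle meshes. Collapses
// are rejected if they would break the local manifold structure (link
// condition) or flip the orientation of an incident triangle, so a
// closed input stays closed.

namespace {

struct Quadric {
  // symmetric 4x4: a11 a12 a13 a14 a22 a23 a24 a33 a34 a44
  double q[10] = {0, 0, 0, 0, 0, 0, 0, 0, 0, 0};
  void add_plane(double a, double b, double c, double d, double w) {
    q[0] += w * a * a; q[1] += w * a * b; q[2] += w * a * c; q[3] += w * a * d;
    q[4] += w * b * b; q[5] += w * b * c; q[6] += w * b * d;
    q[7] += w * c * c; q[8] += w * c * d;
    q[9] += w * d * d;
  }
  void add(const Quadric& o) {
    for (int i = 0; i < 10; ++i) q[i] += o.q[i];
  }
  double eval(double x, double y, double z) const {
    return q[0] * x * x + 2 * q[1] * x * y + 2 * q[2] * x * z + 2 * q[3] * x +
           q[4] * y * y + 2 * q[5] * y * z + 2 * q[6] * y +
           q[7] * z * z + 2 * q[8] * z + q[9];
  }
  // minimise the quadratic form; false if the 3x3 system is singular
  bool minimum(double& x, double& y, double& z) const {
    double a = q[0], b = q[1], c = q[2], d = q[4], e = q[5], f = q[7];
    double det = a * (d * f - e * e) - b * (b * f - c * e) +
                 c * (b * e - c * d);
    double scale = std::fabs(a) + std::fabs(d) + std::fabs(f) + 1e-300;
    if (std::fabs(det) < 1e-10 * scale * scale * scale) return false;
    double rx = -q[3], ry = -q[6], rz = -q[8];
    x = (rx * (d * f - e * e) - b * (ry * f - rz * e) +
         c * (ry * e - rz * d)) / det;
    y = (a * (ry * f - rz * e) - rx * (b * f - c * e) +
         c * (b * rz - c * ry)) / det;
    z = (a * (d * rz - e * ry) - b * (b * rz - c * ry) +
         rx * (b * e - c * d)) / det;
    return true;
  }
};

struct HeapEntry {
  double cost;
  int a, b;
  uint32_t va, vb;  // vertex versions at push time
  bool operator<(const HeapEntry& o) const { return cost > o.cost; }
};

}  // namespace

// [[Rcpp::export]]
List cpp_decimate_qem(NumericMatrix Vin, IntegerMatrix Fin, int target_tris) {
  int nv = Vin.nrow();
  int nt = Fin.nrow();
  std::vector<double> X(nv), Y(nv), Z(nv);
  for (int i = 0; i < nv; ++i) {
    X[i] = Vin(i, 0); Y[i] = Vin(i, 1); Z[i] = Vin(i, 2);
  }
  std::vector<std::array<int, 3>> F(nt);
  std::vector<bool> fdead(nt, false), vdead(nv, false);
  std::vector<std::vector<int>> vfaces(nv);
  for (int t = 0; t < nt; ++t) {
    F[t] = {Fin(t, 0) - 1, Fin(t, 1) - 1, Fin(t, 2) - 1};
    for (int e = 0; e < 3; ++e) vfaces[F[t][e]].push_back(t);
  }

  auto fnormal = [&](int t, double px, double py, double pz, int vrepl,
                     double* n) {
    // normal of face t with vertex vrepl (or -1) moved to (px,py,pz)
    double p[3][3];
    for (int e = 0; e < 3; ++e) {
      int v = F[t][e];
      if (v == vrepl) {
        p[e][0] = px; p[e][1] = py; p[e][2] = pz;
      } else {
        p[e][0] = X[v]; p[e][1] = Y[v]; p[e][2] = Z[v];
      }
    }
    double ux = p[1][0] - p[0][0], uy = p[1][1] - p[0][1],
           uz = p[1][2] - p[0][2];
    double wx = p[2][0] - p[0][0], wy = p[2][1] - p[0][1],
           wz = p[2][2] - p[0][2];
    n[0] = uy * wz - uz * wy;
    n[1] = uz * wx - ux * wz;
    n[2] = ux * wy - uy * wx;
  };

  // initial vertex quadrics, area-weighted
  std::vector<Quadric> Q(nv);
  for (int t = 0; t < nt; ++t) {
    double n[3];
    fnormal(t, 0, 0, 0, -1, n);
    double len = std::sqrt(n[0] * n[0] + n[1] * n[1] + n[2] * n[2]);
    if (len < 1e-300) continue;
    double area = 0.5 * len;
    double a = n[0] / len, b = n[1] / len, c = n[2] / len;
    int v0 = F[t][0];
    double d = -(a * X[v0] + b * Y[v0] + c * Z[v0]);
    for (int e = 0; e < 3; ++e) Q[F[t][e]].add_plane(a, b, c, d, area);
  }

  std::vector<uint32_t> version(nv, 0);
  std::priority_queue<HeapEntry> heap;

  auto neighbors = [&](int v) {
    std::set<int> nb;
    for (int t : vfaces[v]) {
      if (fdead[t]) continue;
      for (int e = 0; e < 3; ++e)
        if (F[t][e] != v) nb.insert(F[t][e]);
    }
    return nb;
  };

  auto best_position = [&](int a, int b, double& px, double& py, double& pz,
                           double& cost) {
    Quadric q = Q[a];
    q.add(Q[b]);
    double ox, oy, oz;
    double mx = 0.5 * (X[a] + X[b]), my = 0.5 * (Y[a] + Y[b]),
           mz = 0.5 * (Z[a] + Z[b]);
    px = mx; py = my; pz = mz;
    cost = q.eval(mx, my, mz);
    double ca = q.eval(X[a], Y[a], Z[a]);
    if (ca < cost) { cost = ca; px = X[a]; py = Y[a]; pz = Z[a]; }
    double cb = q.eval(X[b], Y[b], Z[b]);
    if (cb < cost) { cost = cb; px = X[b]; py = Y[b]; pz = Z[b]; }
    if (q.minimum(ox, oy, oz)) {
      // reject wild optimal points far outside the edge neighbourhood
      double el2 = (X[a] - X[b]) * (X[a] - X[b]) +
                   (Y[a] - Y[b]) * (Y[a] - Y[b]) +
                   (Z[a] - Z[b]) * (Z[a] - Z[b]);
      double d2 = (ox - mx) * (ox - mx) + (oy - my) * (oy - my) +
                  (oz - mz) * (oz - mz);
      double co = q.eval(ox, oy, oz);
      if (d2 <= 25.0 * el2 + 1e-12 && co < cost) {
        cost = co; px = ox; py = oy; pz = oz;
      }
    }
  };

  auto push_edges_of = [&](int v) {
    for (int u : neighbors(v)) {
      int a = std::min(u, v), b = std::max(u, v);
      double px, py, pz, cost;
      best_position(a, b, px, py, pz, cost);
      heap.push({cost, a, b, version[a], version[b]});
    }
  };
  for (int v = 0; v < nv; ++v) {
    for (int u : neighbors(v))
      if (u > v) {
        double px, py, pz, cost;
        best_position(v, u, px, py, pz, cost);
        heap.push({cost, v, u, version[v], version[u]});
      }
  }

  int live = nt;
  while (live > target_tris && !heap.empty()) {
    HeapEntry e = heap.top();
    heap.pop();
    int a = e.a, b = e.b;
    if (vdead[a] || vdead[b]) continue;
    if (version[a] != e.va || version[b] != e.vb) continue;

    // still an edge?
    std::set<int> na = neighbors(a);
    if (!na.count(b)) continue;
    // link condition: shared neighbours must be exactly the two
    // opposite vertices of the (two) faces on edge (a,b)
    std::set<int> nb = neighbors(b);
    int shared = 0;
    for (int u : na)
      if (nb.count(u)) ++shared;
    int edge_faces = 0;
    for (int t : vfaces[a]) {
      if (fdead[t]) continue;
      bool hasb = false;
      for (int k = 0; k < 3; ++k)
        if (F[t][k] == b) hasb = true;
      if (hasb) ++edge_faces;
    }
    if (edge_faces != 2 || shared != 2) continue;

    double px, py, pz, cost;
    best_position(a, b, px, py, pz, cost);

    // orientation guard: no surviving incident face may flip
    bool flip = false;
    for (int pass = 0; pass < 2 && !flip; ++pass) {
      int v = pass == 0 ? a : b;
      int other = pass == 0 ? b : a;
      for (int t : vfaces[v]) {
        if (fdead[t]) continue;
        bool dies = false;
        for (int k = 0; k < 3; ++k)
          if (F[t][k] == other) dies = true;
        if (dies) continue;
        double n0[3], n1[3];
        fnormal(t, 0, 0, 0, -1, n0);
        fnormal(t, px, py, pz, v, n1);
        double dot = n0[0] * n1[0] + n0[1] * n1[1] + n0[2] * n1[2];
        double l0 = std::sqrt(n0[0] * n0[0] + n0[1] * n0[1] + n0[2] * n0[2]);
        double l1 = std::sqrt(n1[0] * n1[0] + n1[1] * n1[1] + n1[2] * n1[2]);
        if (l1 < 1e-12 * (l0 + 1e-300) || dot <= 0) {
          flip = true;
          break;
        }
      }
    }
    if (flip) continue;

    // collapse b into a
    X[a] = px; Y[a] = py; Z[a] = pz;
    Q[a].add(Q[b]);
    vdead[b] = true;
    for (int t : vfaces[b]) {
      if (fdead[t]) continue;
      bool hasa = false;
      for (int k = 0; k < 3; ++k)
        if (F[t][k] == a) hasa = true;
      if (hasa) {
        fdead[t] = true;
        --live;
      } else {
        for (int k = 0; k < 3; ++k)
          if (F[t][k] == b) F[t][k] = a;
        vfaces[a].push_back(t);
      }
    }
    vfaces[b].clear();
    ++version[a];
    ++version[b];
    push_edges_of(a);
  }

  // compact
  std::vector<int> remap(nv, -1);
  int nv2 = 0;
  for (int v = 0; v < nv; ++v)
    if (!vdead[v]) remap[v] = nv2++;
  NumericMatrix Vout(nv2, 3);
  for (int v = 0; v < nv; ++v)
    if (remap[v] >= 0) {
      Vout(remap[v], 0) = X[v];
      Vout(remap[v], 1) = Y[v];
      Vout(remap[v], 2) = Z[v];
    }
  IntegerMatrix Fout(live, 3);
  int r = 0;
  for (int t = 0; t < nt; ++t) {
    if (fdead[t]) continue;
    for (int k = 0; k < 3; ++k) Fout(r, k) = remap[F[t][k]] + 1;
    ++r;
  }
  return List::create(_["vertices"] = Vout, _["triangles"] = Fout);
}
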