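#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <limits>
using namespace Rcpp;

// Column-wise material extents of a 3D binary grid: for every (x,y)
// column the first and last TRUE z-index (1-based), or 0 when empty.
// [[Rcpp::export]]
List cpp_column_extents(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  IntegerMatrix top(nx, ny), bottom(nx, ny);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      int lo = 0, hi = 0;
      for (int k = 0; k < nz; ++k) {
        if (mask[(R_xlen_t)k * nxy + (R_xlen_t)j * nx + i]) {
          if (lo == 0) lo = k + 1;
          hi = k + 1;
        }
      }
      bottom(i, j) = lo;
      top(i, j) = hi;
    }
  return List::create(_["bottom"] = bottom, _["top"] = top);
}

// Fill missing cells of a 2D height map by breadth-first
// neighbour-mean infill: cells adjacent to known values are assigned
// the mean of their (8-neighbourhood) known neighbours, layer by
// layer, restricted to `domain`. Deterministic; an unbiased local
// interpolator for surfaces sampled on a staircase lattice.
// [[Rcpp::export]]
NumericMatrix cpp_fill_heights(NumericMatrix h, LogicalMatrix known,
                               LogicalMatrix domain) {
  int nx = h.nrow(), ny = h.ncol();
  NumericMatrix out(clone(h));
  std::vector<char> kn(nx * ny);
  std::vector<int> frontier, next;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      kn[j * nx + i] = known(i, j) ? 1 : 0;
  // initial frontier: unknown domain cells with a known neighbour
  auto has_known = [&](int i, int j) {
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0) continue;
        int ii = i + di, jj = j + dj;
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny) continue;
        if (kn[jj * nx + ii]) return true;
      }
    return false;
  };
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      if (domain(i, j) && !kn[j * nx + i] && has_known(i, j))
        frontier.push_back(j * nx + i);
  while (!frontier.empty()) {
    std::vector<double> vals(frontier.size());
    for (size_t f = 0; f < frontier.size(); ++f) {
      int i = frontier[f] % nx, j = frontier[f] / nx;
      double s = 0;
      int n = 0;
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0) continue;
          int ii = i + di, jj = j + dj;
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny) continue;
          if (kn[jj * nx + ii]) {
            s += out(ii, jj);
            ++n;
          }
        }
      vals[f] = n > 0 ? s / n : NA_REAL;
    }
    for (size_t f = 0; f < frontier.size(); ++f) {
      int i = frontier[f] % nx, j = frontier[f] / nx;
      out(i, j) = vals[f];
      kn[frontier[f]] = 1;
    }
    next.clear();
    for (size_t f = 0; f < frontier.size(); ++f) {
      int i = frontier[f] % nx, j = frontier[f] / nx;
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          int ii = i + di, jj = j + dj;
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny) continue;
          int id = jj * nx + ii;
          if (domain(ii, jj) && !kn[id]) {
            kn[id] = 2;  // queued
            next.push_back(id);
          }
        }
    }
    // reset queued marker to unknown but deduplicated
    for (int id : next) kn[id] = 0;
    std::sort(next.begin(), next.end());
    next.erase(std::unique(next.begin(), next.end()), next.end());
    // only keep cells that now have a known neighbour
    frontier.clear();
    for (int id : next) {
      int i = id % nx, j = id / nx;
      if (has_known(i, j)) frontier.push_back(id);
    }
  }
  return out;
}

// Flat grayscale dilation (max filter) of a 2D map over a disc of
// radius r pixels. -Inf cells act as missing values.
// [[Rcpp::export]]
NumericMatrix cpp_disc_max(NumericMatrix m, double r) {
  int nx = m.nrow(), ny = m.ncol();
  int ri = (int)std::floor(r);
  std::vector<std::pair<int, int>> offs;
  for (int dj = -ri; dj <= ri; ++dj)
    for (int di = -ri; di <= ri; ++di)
      if ((double)di * di + (double)dj * dj <= r * r + 1e-9)
        offs.emplace_back(di, dj);
  NumericMatrix out(nx, ny);
  double ninf = -std::numeric_limits<double>::infinity();
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      double best = ninf;
      for (const auto& o : offs) {
        int ii = i + o.first, jj = j + o.second;
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny) continue;
        double v = m(ii, jj);
        if (v > best) best = v;
      }
      out(i, j) = best;
    }
  return out;
}
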