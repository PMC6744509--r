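#include <Rcpp.h>
#include <queue>
#include <limits>
#include <vector>
using namespace Rcpp;

// 3D binary image kernels shared by the segmentation, post-processing and
// surface-distance code. All masks are passed as logical vectors in R's
// column-major layout with an explicit dim; borders are zero-padded.

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// [[Rcpp::export]]
LogicalVector cpp_dilate_cube(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out(mask.size());
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        bool hit = false;
        for (int dz = -1; dz <= 1 && !hit; ++dz)
          for (int dy = -1; dy <= 1 && !hit; ++dy)
            for (int dx = -1; dx <= 1 && !hit; ++dx) {
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
                continue;  // zero padding: outside contributes background
              if (mask[idx3(xx, yy, zz, nx, ny)]) hit = true;
            }
        out[idx3(x, y, z, nx, ny)] = hit;
      }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_erode_cube(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out(mask.size());
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        bool all = true;
        for (int dz = -1; dz <= 1 && all; ++dz)
          for (int dy = -1; dy <= 1 && all; ++dy)
            for (int dx = -1; dx <= 1 && all; ++dx) {
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) {
                all = false;  // zero padding: border voxels erode
                continue;
              }
              if (!mask[idx3(xx, yy, zz, nx, ny)]) all = false;
            }
        out[idx3(x, y, z, nx, ny)] = all;
      }
  return out;
}

// Label connected components; connectivity 6 (faces) or 26 (full cube).
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = mask.size();
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<int> stack;
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    stack.push_back(i);
    lab[i] = next;
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int z = cur / (nx * ny), r = cur % (nx * ny);
      int y = r / nx, x = r % nx;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int ad = std::abs(dx) + std::abs(dy) + std::abs(dz);
            if (ad == 0) continue;
            if (connectivity == 6 && ad != 1) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
              continue;
            int j = idx3(xx, yy, zz, nx, ny);
            if (mask[j] && lab[j] == 0) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
    }
  }
  return lab;
}

// 6-connected flood fill of `accept` from 0-based linear seed indices.
// [[Rcpp::export]]
LogicalVector cpp_flood_fill6(LogicalVector accept, IntegerVector dim,
                              IntegerVector seeds) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out(accept.size(), false);
  std::vector<int> stack;
  for (int s = 0; s < seeds.size(); ++s) {
    int i = seeds[s];
    if (i < 0 || i >= accept.size() || !accept[i] || out[i]) continue;
    out[i] = true;
    stack.push_back(i);
  }
  const int step[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  while (!stack.empty()) {
    int cur = stack.back();
    stack.pop_back();
    int z = cur / (nx * ny), r = cur % (nx * ny);
    int y = r / nx, x = r % nx;
    for (int d = 0; d < 6; ++d) {
      int xx = x + step[d][0], yy = y + step[d][1], zz = z + step[d][2];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
        continue;
      int j = idx3(xx, yy, zz, nx, ny);
      if (accept[j] && !out[j]) {
        out[j] = true;
        stack.push_back(j);
      }
    }
  }
  return out;
}

// 1D squared-distance transform (lower envelope of parabolas) with sample
// spacing s; the Felzenszwalb-Huttenlocher algorithm on positions x_i = i*s.
static void dt1d(std::vector<double> &f, double s) {
  int n = (int)f.size();
  std::vector<double> d(n);
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  zb[0] = -INF;
  zb[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double xq = q * s;
    while (true) {
      if (f[v[k]] == INF) {  // drop unreachable parabola
        if (k == 0) { v[0] = q; zb[0] = -INF; zb[1] = INF; goto placed; }
        --k;
        continue;
      }
      double xv = v[k] * s;
      double sN = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (sN <= zb[k]) {
        --k;
      } else {
        ++k;
        v[k] = q;
        zb[k] = sN;
        zb[k + 1] = INF;
        break;
      }
    }
    placed:;
  }
  if (f[v[0]] == INF) {  // no finite source on this line
    for (int q = 0; q < n; ++q) d[q] = INF;
  } else {
    int j = 0;
    for (int q = 0; q < n; ++q) {
      double xq = q * s;
      while (zb[j + 1] < xq) ++j;
      double xv = v[j] * s;
      d[q] = (xq - xv) * (xq - xv) + f[v[j]];
    }
  }
  f = d;
}

// Exact squared Euclidean distance (in mm when spacing given, else voxels)
// from every voxel to the nearest true voxel of `mask`. Inf if mask empty.
// [[Rcpp::export]]
NumericVector cpp_edt_squared(LogicalVector mask, IntegerVector dim,
                              NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector g(mask.size());
  for (int i = 0; i < mask.size(); ++i) g[i] = mask[i] ? 0.0 : INF;

  std::vector<double> line;
  // x pass
  line.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) line[x] = g[idx3(x, y, z, nx, ny)];
      dt1d(line, spacing[0]);
      for (int x = 0; x < nx; ++x) g[idx3(x, y, z, nx, ny)] = line[x];
    }
  // y pass
  line.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) line[y] = g[idx3(x, y, z, nx, ny)];
      dt1d(line, spacing[1]);
      for (int y = 0; y < ny; ++y) g[idx3(x, y, z, nx, ny)] = line[y];
    }
  // z pass
  line.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) line[z] = g[idx3(x, y, z, nx, ny)];
      dt1d(line, spacing[2]);
      for (int z = 0; z < nz; ++z) g[idx3(x, y, z, nx, ny)] = line[z];
    }
  return g;
}

// Border voxels: mask voxels with at least one 6-neighbor outside the mask
// (volume borders count as outside).
// [[Rcpp::export]]
LogicalVector cpp_surface_voxels(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out(mask.size(), false);
  const int step[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = idx3(x, y, z, nx, ny);
        if (!mask[i]) continue;
        for (int d = 0; d < 6; ++d) {
          int xx = x + step[d][0], yy = y + step[d][1], zz = z + step[d][2];
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz ||
              !mask[idx3(xx, yy, zz, nx, ny)]) {
            out[i] = true;
            break;
          }
        }
      }
  return out;
}
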