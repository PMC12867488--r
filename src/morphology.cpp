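#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Arrays are R arrays with dim = (z, y, x); linear index = z + nz*(y + ny*x).

static inline R_xlen_t lin(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)x);
}

// Connected-component labelling by breadth-first search.
// connectivity: 6 (faces), 18 (faces+edges), 26 (faces+edges+corners).
// Labels are assigned in raster-scan discovery order starting at 1;
// relabelling by component size happens on the R side.
// [[Rcpp::export(name = ".cc_label3d")]]
IntegerVector cc_label3d(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  std::vector<int> odz, ody, odx;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        odz.push_back(dz); ody.push_back(dy); odx.push_back(dx);
      }
  const int noff = (int)odz.size();

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> queue;
  int next_label = 0;

  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = lin(z, y, x, nz, ny);
        if (!mask[i] || labels[i] != 0) continue;
        ++next_label;
        labels[i] = next_label;
        queue.clear();
        queue.push_back(i);
        while (!queue.empty()) {
          R_xlen_t j = queue.back();
          queue.pop_back();
          int jx = (int)(j / ((R_xlen_t)nz * ny));
          R_xlen_t r = j % ((R_xlen_t)nz * ny);
          int jy = (int)(r / nz);
          int jz = (int)(r % nz);
          for (int k = 0; k < noff; ++k) {
            int qz = jz + odz[k], qy = jy + ody[k], qx = jx + odx[k];
            if (qz < 0 || qz >= nz || qy < 0 || qy >= ny || qx < 0 || qx >= nx)
              continue;
            R_xlen_t q = lin(qz, qy, qx, nz, ny);
            if (mask[q] && labels[q] == 0) {
              labels[q] = next_label;
              queue.push_back(q);
            }
          }
        }
      }
  return labels;
}

// --- Euclidean-ball morphology via the separable squared distance
// transform (Felzenszwalb & Huttenlocher). Erosion by a physical ball of
// radius r keeps a foreground voxel iff its nearest background voxel (or
// the volume border, which counts as background) is farther than r;
// dilation marks voxels within r of the foreground. This is exactly the
// erosion/dilation by the discrete anisotropic ball {o : ||o * spacing||
// <= r} at any radius, in O(n) independent of r.

static const double DT_INF = 1e30;

// 1D lower-envelope squared distance transform with sample pitch w
// (parabolas (i-j)^2 * w2 + f[j]). DT_INF is a large finite sentinel, so
// seedless lines fall out of the plain algorithm without special cases.
static void dt1d(const double* f, double* d, int* v, double* zb, int n,
                 double w2) {
  int k = 0;
  v[0] = 0;
  zb[0] = -1e35;
  zb[1] = 1e35;
  for (int q = 1; q < n; ++q) {
    int p = v[k];
    double s = ((f[q] + (double)q * q * w2) - (f[p] + (double)p * p * w2)) /
      (2.0 * w2 * (q - p));
    while (s <= zb[k]) {  // zb[0] = -inf guards k >= 0
      --k;
      p = v[k];
      s = ((f[q] + (double)q * q * w2) - (f[p] + (double)p * p * w2)) /
        (2.0 * w2 * (q - p));
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = 1e35;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    int p = v[k];
    d[q] = (double)(q - p) * (q - p) * w2 + f[p];
  }
}

// Squared distance from every voxel to the seed set, anisotropic spacing.
static void edt3d(std::vector<double>& g, int nz, int ny, int nx,
                  const double* sp) {
  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);
  // pass along z (contiguous)
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      double* col = &g[lin(0, y, x, nz, ny)];
      dt1d(col, d.data(), v.data(), zb.data(), nz, sp[0] * sp[0]);
      std::copy(d.begin(), d.begin() + nz, col);
    }
  // pass along y
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) f[y] = g[lin(z, y, x, nz, ny)];
      dt1d(f.data(), d.data(), v.data(), zb.data(), ny, sp[1] * sp[1]);
      for (int y = 0; y < ny; ++y) g[lin(z, y, x, nz, ny)] = d[y];
    }
  // pass along x
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      for (int x = 0; x < nx; ++x) f[x] = g[lin(z, y, x, nz, ny)];
      dt1d(f.data(), d.data(), v.data(), zb.data(), nx, sp[2] * sp[2]);
      for (int x = 0; x < nx; ++x) g[lin(z, y, x, nz, ny)] = d[x];
    }
}

// [[Rcpp::export(name = ".ball_morph3d")]]
LogicalVector ball_morph3d(LogicalVector mask, IntegerVector dims,
                           NumericVector spacing, double radius_um,
                           bool erode) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dims");
  const double r2 = radius_um * radius_um + 1e-9;

  LogicalVector out(n);
  if (erode) {
    // distance to background, with the volume border padded as background
    const int pz = nz + 2, py = ny + 2, px = nx + 2;
    std::vector<double> g((R_xlen_t)pz * py * px, 0.0);
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y)
        for (int z = 0; z < nz; ++z)
          g[lin(z + 1, y + 1, x + 1, pz, py)] =
            mask[lin(z, y, x, nz, ny)] ? DT_INF : 0.0;
    edt3d(g, pz, py, px, &spacing[0]);
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y)
        for (int z = 0; z < nz; ++z)
          out[lin(z, y, x, nz, ny)] =
            mask[lin(z, y, x, nz, ny)] &&
            g[lin(z + 1, y + 1, x + 1, pz, py)] > r2;
  } else {
    std::vector<double> g(n);
    for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? 0.0 : DT_INF;
    edt3d(g, nz, ny, nx, &spacing[0]);
    for (R_xlen_t i = 0; i < n; ++i) out[i] = g[i] <= r2;
  }
  return out;
}

// Mark voxels within `radius_um` of any of k straight lines, restricted to a
// domain mask (the brain). Lines are given by a point (p0, um) and a unit
// direction per column; voxel physical position = origin + index * spacing.
// [[Rcpp::export(name = ".tube_mask3d")]]
LogicalVector tube_mask3d(IntegerVector dims, NumericVector spacing,
                          NumericVector origin, NumericMatrix p0,
                          NumericMatrix dir, double radius_um,
                          LogicalVector domain) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (domain.size() != n) stop("domain length does not match dims");
  const int k = p0.ncol();
  const double r2 = radius_um * radius_um;
  LogicalVector out(n, false);

  for (int x = 0; x < nx; ++x) {
    double px = origin[2] + x * spacing[2];
    for (int y = 0; y < ny; ++y) {
      double py = origin[1] + y * spacing[1];
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = lin(z, y, x, nz, ny);
        if (!domain[i]) continue;
        double pz = origin[0] + z * spacing[0];
        for (int t = 0; t < k; ++t) {
          double vz = pz - p0(0, t), vy = py - p0(1, t), vx = px - p0(2, t);
          double proj = vz * dir(0, t) + vy * dir(1, t) + vx * dir(2, t);
          double dz = vz - proj * dir(0, t);
          double dy = vy - proj * dir(1, t);
          double dx = vx - proj * dir(2, t);
          if (dz * dz + dy * dy + dx * dx <= r2) {
            out[i] = true;
            break;
          }
        }
      }
    }
  }
  return out;
}
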