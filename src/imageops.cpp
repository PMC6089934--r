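// 3D image primitives: exact Euclidean distance transform, local thickness by
// inscribed-sphere painting, distance-ridge extraction, cubic median and box
// filters, and connected-component labeling. All arrays are column-major with
// dim (nx, ny, nz); a single-slice volume (nz = 1) degenerates to the 2D case.
// Voxels outside the array are treated as neither foreground nor background.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
#include <algorithm>
using namespace Rcpp;

static const double DT_INF = 1e20;

// Felzenszwalb-Huttenlocher 1D squared distance transform (lower envelope of
// parabolas); f holds squared distances, result written back into f.
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Squared Euclidean distance (voxel units) from every voxel to the nearest
// TRUE voxel of `mask`; DT_INF if the mask is empty.
// [[Rcpp::export]]
NumericVector cpp_sedt(LogicalVector mask, int nx, int ny, int nz) {
  const size_t n = (size_t)nx * ny * nz;
  NumericVector D(n);
  for (size_t i = 0; i < n; ++i) D[i] = mask[i] ? 0.0 : DT_INF;
  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // along x
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy) {
      double* line = REAL(D) + (size_t)nx * (iy + (size_t)ny * iz);
      for (int i = 0; i < nx; ++i) f[i] = line[i];
      dt1d(f, d, v, z, nx);
      for (int i = 0; i < nx; ++i) line[i] = f[i];
    }
  // along y
  for (int iz = 0; iz < nz; ++iz)
    for (int ix = 0; ix < nx; ++ix) {
      double* base = REAL(D) + ix + (size_t)nx * ny * iz;
      for (int i = 0; i < ny; ++i) f[i] = base[(size_t)nx * i];
      dt1d(f, d, v, z, ny);
      for (int i = 0; i < ny; ++i) base[(size_t)nx * i] = f[i];
    }
  // along z
  if (nz > 1)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        double* base = REAL(D) + ix + (size_t)nx * iy;
        for (int i = 0; i < nz; ++i) f[i] = base[(size_t)nx * ny * i];
        dt1d(f, d, v, z, nz);
        for (int i = 0; i < nz; ++i) base[(size_t)nx * ny * i] = f[i];
      }
  return D;
}

// Local thickness: every foreground voxel gets the diameter (voxel units) of
// the largest inscribed sphere containing it. A sphere centered at c has
// radius r_c = distance to the nearest background voxel center; it covers
// voxels v with |v - c| < r_c and its reported diameter is 2 r_c - 1 (equal to
// the slab width for odd slabs, one voxel short for even ones). Painting from
// every foreground center realizes the definition exactly.
// [[Rcpp::export]]
NumericVector cpp_local_thickness(LogicalVector mask, int nx, int ny, int nz) {
  const size_t n = (size_t)nx * ny * nz;
  LogicalVector bg(n);
  for (size_t i = 0; i < n; ++i) bg[i] = !mask[i];
  NumericVector r2 = cpp_sedt(bg, nx, ny, nz);
  NumericVector th(n);
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        const size_t c = ix + (size_t)nx * (iy + (size_t)ny * iz);
        if (!mask[c]) continue;
        const double rc2 = r2[c];
        if (rc2 >= DT_INF) continue;  // no background anywhere
        const double rc = std::sqrt(rc2);
        const double dia = 2.0 * rc - 1.0;
        const int R = (int)std::ceil(rc);
        const int z0 = std::max(0, iz - R), z1 = std::min(nz - 1, iz + R);
        const int y0 = std::max(0, iy - R), y1 = std::min(ny - 1, iy + R);
        const int x0 = std::max(0, ix - R), x1 = std::min(nx - 1, ix + R);
        for (int vz = z0; vz <= z1; ++vz) {
          const double dz2 = (vz - iz) * (double)(vz - iz);
          for (int vy = y0; vy <= y1; ++vy) {
            const double dyz2 = dz2 + (vy - iy) * (double)(vy - iy);
            if (dyz2 >= rc2) continue;
            double* row = REAL(th) + (size_t)nx * (vy + (size_t)ny * vz);
            for (int vx = x0; vx <= x1; ++vx) {
              const double d2 = dyz2 + (vx - ix) * (double)(vx - ix);
              if (d2 < rc2 && row[vx] < dia) row[vx] = dia;
            }
          }
        }
      }
  return th;
}

// Distance-ridge voxels: foreground voxels whose distance-to-background is a
// local maximum over the 26-neighborhood (plateaus included). Used as
// skeleton-like seeds for the ellipsoid factor.
// [[Rcpp::export]]
LogicalVector cpp_distance_ridge(LogicalVector mask, int nx, int ny, int nz) {
  const size_t n = (size_t)nx * ny * nz;
  LogicalVector bg(n);
  for (size_t i = 0; i < n; ++i) bg[i] = !mask[i];
  NumericVector r2 = cpp_sedt(bg, nx, ny, nz);
  LogicalVector ridge(n);
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        const size_t c = ix + (size_t)nx * (iy + (size_t)ny * iz);
        if (!mask[c]) { ridge[c] = false; continue; }
        bool ismax = true;
        for (int dz = -1; dz <= 1 && ismax; ++dz)
          for (int dy = -1; dy <= 1 && ismax; ++dy)
            for (int dx = -1; dx <= 1 && ismax; ++dx) {
              if (!dx && !dy && !dz) continue;
              const int x = ix + dx, y = iy + dy, z = iz + dz;
              if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz)
                continue;
              if (r2[x + (size_t)nx * (y + (size_t)ny * z)] > r2[c]) ismax = false;
            }
        ridge[c] = ismax;
      }
  return ridge;
}

// Cubic median filter of radius r; the neighborhood is clipped at the borders
// (median over in-bounds voxels only).
// [[Rcpp::export]]
NumericVector cpp_median_filter(NumericVector vol, int nx, int ny, int nz,
                                int r) {
  NumericVector out((size_t)nx * ny * nz);
  std::vector<double> buf((2 * r + 1) * (2 * r + 1) * (2 * r + 1));
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        int m = 0;
        for (int dz = -r; dz <= r; ++dz) {
          const int z = iz + dz;
          if (z < 0 || z >= nz) continue;
          for (int dy = -r; dy <= r; ++dy) {
            const int y = iy + dy;
            if (y < 0 || y >= ny) continue;
            for (int dx = -r; dx <= r; ++dx) {
              const int x = ix + dx;
              if (x < 0 || x >= nx) continue;
              buf[m++] = vol[x + (size_t)nx * (y + (size_t)ny * z)];
            }
          }
        }
        std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
        double med = buf[m / 2];
        if (m % 2 == 0) {
          const double hi = med;
          std::nth_element(buf.begin(), buf.begin() + m / 2 - 1, buf.begin() + m);
          med = 0.5 * (hi + buf[m / 2 - 1]);
        }
        out[ix + (size_t)nx * (iy + (size_t)ny * iz)] = med;
      }
  return out;
}

// Cubic mean (box) filter of radius r, border-clipped and renormalized.
// [[Rcpp::export]]
NumericVector cpp_box_filter(NumericVector vol, int nx, int ny, int nz, int r) {
  NumericVector out((size_t)nx * ny * nz);
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        double s = 0.0;
        int m = 0;
        const int z0 = std::max(0, iz - r), z1 = std::min(nz - 1, iz + r);
        const int y0 = std::max(0, iy - r), y1 = std::min(ny - 1, iy + r);
        const int x0 = std::max(0, ix - r), x1 = std::min(nx - 1, ix + r);
        for (int z = z0; z <= z1; ++z)
          for (int y = y0; y <= y1; ++y)
            for (int x = x0; x <= x1; ++x) {
              s += vol[x + (size_t)nx * (y + (size_t)ny * z)];
              ++m;
            }
        out[ix + (size_t)nx * (iy + (size_t)ny * iz)] = s / m;
      }
  return out;
}

// Connected-component labeling (BFS), connectivity 6 or 26. Labels are
// assigned in lexicographic scan order (x fastest), so label 1 always contains
// the first foreground voxel in scan order -- the documented tie rule for
// despeckling.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, int nx, int ny, int nz,
                                   int connectivity) {
  const size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n);
  std::vector<int> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        if (connectivity == 6 && std::abs(dx) + std::abs(dy) + std::abs(dz) != 1)
          continue;
        offs.push_back(dx);
        offs.push_back(dy);
        offs.push_back(dz);
      }
  int next = 0;
  std::queue<size_t> q;
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        const size_t c = ix + (size_t)nx * (iy + (size_t)ny * iz);
        if (!mask[c] || lab[c]) continue;
        lab[c] = ++next;
        q.push(c);
        while (!q.empty()) {
          const size_t p = q.front();
          q.pop();
          const int pz = p / ((size_t)nx * ny);
          const int py = (p / nx) % ny;
          const int px = p % nx;
          for (size_t o = 0; o < offs.size(); o += 3) {
            const int x = px + offs[o], y = py + offs[o + 1], z = pz + offs[o + 2];
            if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz)
              continue;
            const size_t t = x + (size_t)nx * (y + (size_t)ny * z);
            if (mask[t] && !lab[t]) {
              lab[t] = next;
              q.push(t);
            }
          }
        }
      }
  return lab;
}
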