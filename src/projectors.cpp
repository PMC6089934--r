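// Matrix-free ray-driven (Joseph-style) projectors and pixel-driven
// filtered-backprojection kernels.
//
// Conventions (must match R/geometry.R):
//   * volume arrays are column-major with dim (nx, ny, nz); voxel centers sit
//     at (i - (n-1)/2) voxel units from the rotation axis, i = 0..n-1
//   * all lengths here are in voxel units; callers convert to mm
//   * angles are radians, counter-clockwise; at angle a the parallel ray
//     direction is (cos a, sin a) and the detector axis is (-sin a, cos a)
//   * fan/cone source sits at -sad * (cos a, sin a, 0); the flat detector is
//     perpendicular to the central ray at distance sdd from the source
//   * forward and adjoint share one traversal (template flag), so the pair is
//     adjoint by construction
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trace one line through a 2D slice. q = any point on the ray, d = unit
// direction (both voxel units). Steps across voxel-center planes of the major
// axis with linear interpolation on the transverse axis (Joseph's method).
template <bool ADJ>
static inline double ray2d(double* vol, double g, double qx, double qy,
                           double dx, double dy, int nx, int ny) {
  int nm, nt;
  size_t sm, st;
  double qm, qt, dm, dt;
  if (std::fabs(dx) >= std::fabs(dy)) {
    nm = nx; nt = ny; sm = 1; st = nx;
    qm = qx; qt = qy; dm = dx; dt = dy;
  } else {
    nm = ny; nt = nx; sm = nx; st = 1;
    qm = qy; qt = qx; dm = dy; dt = dx;
  }
  const double dl = 1.0 / std::fabs(dm);
  const double slope = dt / dm;
  // interpolation plane i contributes iff f(i) = qt + (i - qm) * slope lies
  // in [0, nt - 1); solve for the i range and run the interior unguarded
  int ilo = 0, ihi = nm - 1;
  const double tmax = nt - 1 - 1e-9;
  if (slope != 0.0) {
    const double ia = qm + (0.0 - qt) / slope;
    const double ib = qm + (tmax - qt) / slope;
    const double lo = ia < ib ? ia : ib, hi = ia < ib ? ib : ia;
    if (lo > ilo) ilo = (int)std::ceil(lo);
    if (hi < ihi) ihi = (int)std::floor(hi);
  } else if (qt < 0.0 || qt > tmax) {
    return 0.0;
  }
  // guard against rounding at the range ends
  while (ilo <= ihi) {
    const double f = qt + (ilo - qm) * slope;
    if (f < 0.0 || f > tmax) ++ilo; else break;
  }
  while (ihi >= ilo) {
    const double f = qt + (ihi - qm) * slope;
    if (f < 0.0 || f > tmax) --ihi; else break;
  }
  double sum = 0.0;
  double f = qt + (ilo - qm) * slope;
  const double gdl = g * dl;
  for (int i = ilo; i <= ihi; ++i, f += slope) {
    const int j0 = (int)f;
    const double w1 = f - j0;
    double* p = vol + (size_t)i * sm + (size_t)j0 * st;
    if (ADJ) {
      p[0] += gdl * (1.0 - w1);
      p[st] += gdl * w1;
    } else {
      sum += p[0] * (1.0 - w1) + p[st] * w1;
    }
  }
  return sum * dl;
}

// 3D line trace, bilinear interpolation transverse to the major axis.
template <bool ADJ>
static inline double ray3d(double* vol, double g,
                           double qx, double qy, double qz,
                           double dx, double dy, double dz,
                           int nx, int ny, int nz) {
  const double ax = std::fabs(dx), ay = std::fabs(dy), az = std::fabs(dz);
  double sum = 0.0;
  const size_t sx = 1, sy = (size_t)nx, sz = (size_t)nx * ny;
  int nm, na, nb;
  size_t sm, sa, sb;
  double qm, qa, qb, dm, da, db;
  if (ax >= ay && ax >= az) {
    nm = nx; na = ny; nb = nz; sm = sx; sa = sy; sb = sz;
    qm = qx; qa = qy; qb = qz; dm = dx; da = dy; db = dz;
  } else if (ay >= az) {
    nm = ny; na = nx; nb = nz; sm = sy; sa = sx; sb = sz;
    qm = qy; qa = qx; qb = qz; dm = dy; da = dx; db = dz;
  } else {
    nm = nz; na = nx; nb = ny; sm = sz; sa = sx; sb = sy;
    qm = qz; qa = qx; qb = qy; dm = dz; da = dx; db = dy;
  }
  const double dl = 1.0 / std::fabs(dm);
  for (int i = 0; i < nm; ++i) {
    const double t = (i - qm) / dm;
    const double fa = qa + t * da, fb = qb + t * db;
    const int a0 = (int)std::floor(fa), b0 = (int)std::floor(fb);
    const double wa1 = fa - a0, wa0 = 1.0 - wa1;
    const double wb1 = fb - b0, wb0 = 1.0 - wb1;
    for (int db_ = 0; db_ < 2; ++db_) {
      const int b = b0 + db_;
      if (b < 0 || b >= nb) continue;
      const double wb = db_ ? wb1 : wb0;
      for (int da_ = 0; da_ < 2; ++da_) {
        const int a = a0 + da_;
        if (a < 0 || a >= na) continue;
        const double w = wb * (da_ ? wa1 : wa0);
        double* p = vol + (size_t)i * sm + (size_t)a * sa + (size_t)b * sb;
        if (ADJ) *p += g * w * dl; else sum += *p * w;
      }
    }
  }
  return sum * dl;
}

// ---- parallel-beam 2D ----

template <bool ADJ>
static void par2d_run(double* vol, double* sino, int nx, int ny,
                      const NumericVector& angles, int ndet, double pitch) {
  const double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1);
  const double cd = 0.5 * (ndet - 1);
  for (int k = 0; k < angles.size(); ++k) {
    const double ca = std::cos(angles[k]), sa = std::sin(angles[k]);
    for (int j = 0; j < ndet; ++j) {
      const double u = (j - cd) * pitch;
      const double qx = cx - u * sa, qy = cy + u * ca;
      double* s = sino + j + (size_t)ndet * k;
      if (ADJ) ray2d<true>(vol, *s, qx, qy, ca, sa, nx, ny);
      else *s = ray2d<false>(vol, 0.0, qx, qy, ca, sa, nx, ny);
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_par2d_forward(NumericVector vol, int nx, int ny,
                                NumericVector angles, int ndet, double pitch) {
  NumericMatrix sino(ndet, angles.size());
  par2d_run<false>(REAL(vol), REAL(sino), nx, ny, angles, ndet, pitch);
  return sino;
}

// [[Rcpp::export]]
NumericVector cpp_par2d_adjoint(NumericMatrix sino, int nx, int ny,
                                NumericVector angles, int ndet, double pitch) {
  NumericVector vol((R_xlen_t)nx * ny);
  par2d_run<true>(REAL(vol), REAL(sino), nx, ny, angles, ndet, pitch);
  return vol;
}

// ---- fan-beam 2D, flat detector ----

template <bool ADJ>
static void fan2d_run(double* vol, double* sino, int nx, int ny,
                      const NumericVector& angles, int ndet,
                      double pitch_det, double sad, double sdd) {
  const double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1);
  const double cd = 0.5 * (ndet - 1);
  for (int k = 0; k < angles.size(); ++k) {
    const double ca = std::cos(angles[k]), sa = std::sin(angles[k]);
    const double Sx = cx - sad * ca, Sy = cy - sad * sa;
    for (int j = 0; j < ndet; ++j) {
      const double u = (j - cd) * pitch_det;
      // detector element position
      const double Px = Sx + sdd * ca - u * sa;
      const double Py = Sy + sdd * sa + u * ca;
      double dx = Px - Sx, dy = Py - Sy;
      const double nrm = std::sqrt(dx * dx + dy * dy);
      dx /= nrm; dy /= nrm;
      double* s = sino + j + (size_t)ndet * k;
      if (ADJ) ray2d<true>(vol, *s, Sx, Sy, dx, dy, nx, ny);
      else *s = ray2d<false>(vol, 0.0, Sx, Sy, dx, dy, nx, ny);
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_fan2d_forward(NumericVector vol, int nx, int ny,
                                NumericVector angles, int ndet,
                                double pitch_det, double sad, double sdd) {
  NumericMatrix sino(ndet, angles.size());
  fan2d_run<false>(REAL(vol), REAL(sino), nx, ny, angles, ndet, pitch_det, sad, sdd);
  return sino;
}

// [[Rcpp::export]]
NumericVector cpp_fan2d_adjoint(NumericMatrix sino, int nx, int ny,
                                NumericVector angles, int ndet,
                                double pitch_det, double sad, double sdd) {
  NumericVector vol((R_xlen_t)nx * ny);
  fan2d_run<true>(REAL(vol), REAL(sino), nx, ny, angles, ndet, pitch_det, sad, sdd);
  return vol;
}

// ---- cone-beam 3D, flat detector ----

template <bool ADJ>
static void cone3d_run(double* vol, double* sino, int nx, int ny, int nz,
                       const NumericVector& angles, int nu, int nv,
                       double pitch_det, double sad, double sdd) {
  const double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1), cz = 0.5 * (nz - 1);
  const double cu = 0.5 * (nu - 1), cv = 0.5 * (nv - 1);
  const size_t per_view = (size_t)nu * nv;
  for (int k = 0; k < angles.size(); ++k) {
    const double ca = std::cos(angles[k]), sa = std::sin(angles[k]);
    const double Sx = cx - sad * ca, Sy = cy - sad * sa, Sz = cz;
    for (int jv = 0; jv < nv; ++jv) {
      const double v = (jv - cv) * pitch_det;
      for (int ju = 0; ju < nu; ++ju) {
        const double u = (ju - cu) * pitch_det;
        const double Px = Sx + sdd * ca - u * sa;
        const double Py = Sy + sdd * sa + u * ca;
        const double Pz = Sz + v;
        double dx = Px - Sx, dy = Py - Sy, dz = Pz - Sz;
        const double nrm = std::sqrt(dx * dx + dy * dy + dz * dz);
        dx /= nrm; dy /= nrm; dz /= nrm;
        double* s = sino + ju + (size_t)nu * jv + per_view * k;
        if (ADJ) ray3d<true>(vol, *s, Sx, Sy, Sz, dx, dy, dz, nx, ny, nz);
        else *s = ray3d<false>(vol, 0.0, Sx, Sy, Sz, dx, dy, dz, nx, ny, nz);
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_cone3d_forward(NumericVector vol, int nx, int ny, int nz,
                                 NumericVector angles, int nu, int nv,
                                 double pitch_det, double sad, double sdd) {
  NumericVector sino((R_xlen_t)nu * nv * angles.size());
  cone3d_run<false>(REAL(vol), REAL(sino), nx, ny, nz, angles, nu, nv,
                    pitch_det, sad, sdd);
  return sino;
}

// [[Rcpp::export]]
NumericVector cpp_cone3d_adjoint(NumericVector sino, int nx, int ny, int nz,
                                 NumericVector angles, int nu, int nv,
                                 double pitch_det, double sad, double sdd) {
  NumericVector vol((R_xlen_t)nx * ny * nz);
  cone3d_run<true>(REAL(vol), REAL(sino), nx, ny, nz, angles, nu, nv,
                   pitch_det, sad, sdd);
  return vol;
}

// ---- pixel-driven backprojectors for FBP/FDK ----
// q is the filtered (and pre-weighted) sinogram; the caller applies the
// angular step / short-scan normalization.

// [[Rcpp::export]]
NumericVector cpp_bp_par2d(NumericMatrix q, int nx, int ny,
                           NumericVector angles, double pitch) {
  const int ndet = q.nrow();
  const double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1);
  const double cd = 0.5 * (ndet - 1);
  NumericVector vol((R_xlen_t)nx * ny);
  for (int k = 0; k < angles.size(); ++k) {
    const double ca = std::cos(angles[k]), sa = std::sin(angles[k]);
    const double* qk = &q(0, k);
    for (int iy = 0; iy < ny; ++iy) {
      const double y = iy - cy;
      for (int ix = 0; ix < nx; ++ix) {
        const double x = ix - cx;
        const double u = -x * sa + y * ca;
        const double jf = u / pitch + cd;
        const int j0 = (int)std::floor(jf);
        if (j0 < 0 || j0 + 1 >= ndet) continue;
        const double w1 = jf - j0;
        vol[ix + (size_t)nx * iy] += qk[j0] * (1.0 - w1) + qk[j0 + 1] * w1;
      }
    }
  }
  return vol;
}

// Fan-beam weighted backprojection; detector coordinate rescaled to the
// isocenter (pitch_iso = pitch_det * sad / sdd), weight sad^2 / L^2 where L is
// the distance from the source along the central-ray direction.
// [[Rcpp::export]]
NumericVector cpp_bp_fan2d(NumericMatrix q, int nx, int ny,
                           NumericVector angles, double pitch_iso, double sad) {
  const int ndet = q.nrow();
  const double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1);
  const double cd = 0.5 * (ndet - 1);
  NumericVector vol((R_xlen_t)nx * ny);
  for (int k = 0; k < angles.size(); ++k) {
    const double ca = std::cos(angles[k]), sa = std::sin(angles[k]);
    const double* qk = &q(0, k);
    for (int iy = 0; iy < ny; ++iy) {
      const double y = iy - cy;
      for (int ix = 0; ix < nx; ++ix) {
        const double x = ix - cx;
        const double L = sad + x * ca + y * sa;
        if (L <= 1e-9) continue;
        const double t = -x * sa + y * ca;
        const double u = t * sad / L;
        const double jf = u / pitch_iso + cd;
        const int j0 = (int)std::floor(jf);
        if (j0 < 0 || j0 + 1 >= ndet) continue;
        const double w1 = jf - j0;
        const double w = sad * sad / (L * L);
        vol[ix + (size_t)nx * iy] += w * (qk[j0] * (1.0 - w1) + qk[j0 + 1] * w1);
      }
    }
  }
  return vol;
}

// FDK cone-beam weighted backprojection; detector coordinates rescaled to the
// isocenter.
// [[Rcpp::export]]
NumericVector cpp_bp_cone3d(NumericVector q, int nu, int nv, int nx, int ny,
                            int nz, NumericVector angles, double pitch_iso,
                            double sad) {
  const double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1), cz = 0.5 * (nz - 1);
  const double cu = 0.5 * (nu - 1), cv = 0.5 * (nv - 1);
  NumericVector vol((R_xlen_t)nx * ny * nz);
  const size_t per_view = (size_t)nu * nv;
  for (int k = 0; k < angles.size(); ++k) {
    const double ca = std::cos(angles[k]), sa = std::sin(angles[k]);
    const double* qk = REAL(q) + per_view * k;
    for (int iz = 0; iz < nz; ++iz) {
      const double z = iz - cz;
      for (int iy = 0; iy < ny; ++iy) {
        const double y = iy - cy;
        for (int ix = 0; ix < nx; ++ix) {
          const double x = ix - cx;
          const double L = sad + x * ca + y * sa;
          if (L <= 1e-9) continue;
          const double t = -x * sa + y * ca;
          const double uf = (t * sad / L) / pitch_iso + cu;
          const double vf = (z * sad / L) / pitch_iso + cv;
          const int u0 = (int)std::floor(uf), v0 = (int)std::floor(vf);
          if (u0 < 0 || u0 + 1 >= nu || v0 < 0 || v0 + 1 >= nv) continue;
          const double wu1 = uf - u0, wv1 = vf - v0;
          const double g =
            qk[u0 + (size_t)nu * v0] * (1 - wu1) * (1 - wv1) +
            qk[u0 + 1 + (size_t)nu * v0] * wu1 * (1 - wv1) +
            qk[u0 + (size_t)nu * (v0 + 1)] * (1 - wu1) * wv1 +
            qk[u0 + 1 + (size_t)nu * (v0 + 1)] * wu1 * wv1;
          vol[ix + (size_t)nx * (iy + (size_t)ny * iz)] += g * sad * sad / (L * L);
        }
      }
    }
  }
  return vol;
}
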