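#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Numerical kernels for the filament-coil and surface-charge computations.
// All kernels are geometry-only: physical prefactors (mu0, I0, 1/(4*pi)) are
// applied by the R callers so that every quantity is scaled in exactly one
// place.

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void cross3(const double* a, const double* b, double* c) {
  c[0] = a[1] * b[2] - a[2] * b[1];
  c[1] = a[2] * b[0] - a[0] * b[2];
  c[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }

// Fields of a set of straight current filaments at observation points,
// midpoint (point-moment) rule per segment:
//   A-sum = sum_m w_m s_m / |r - c_m|
//   B-sum = sum_m w_m s_m x (r - c_m) / |r - c_m|^3
// where c_m is the segment midpoint and s_m its directed vector.
// [[Rcpp::export]]
List cpp_filament_fields(NumericMatrix seg_start, NumericMatrix seg_end,
                         NumericVector w, NumericMatrix pts, double guard) {
  const int m = seg_start.nrow(), n = pts.nrow();
  NumericMatrix A(n, 3), B(n, 3);
  std::vector<double> cx(m), cy(m), cz(m), sx(m), sy(m), sz(m);
  for (int j = 0; j < m; ++j) {
    cx[j] = 0.5 * (seg_start(j, 0) + seg_end(j, 0));
    cy[j] = 0.5 * (seg_start(j, 1) + seg_end(j, 1));
    cz[j] = 0.5 * (seg_start(j, 2) + seg_end(j, 2));
    sx[j] = w[j] * (seg_end(j, 0) - seg_start(j, 0));
    sy[j] = w[j] * (seg_end(j, 1) - seg_start(j, 1));
    sz[j] = w[j] * (seg_end(j, 2) - seg_start(j, 2));
  }
  for (int i = 0; i < n; ++i) {
    double ax = 0, ay = 0, az = 0, bx = 0, by = 0, bz = 0;
    const double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    for (int j = 0; j < m; ++j) {
      const double dx = px - cx[j], dy = py - cy[j], dz = pz - cz[j];
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < guard * guard)
        stop("observation point %d lies on (or within the guard distance of) filament %d",
             i + 1, j + 1);
      const double r = std::sqrt(r2), ir = 1.0 / r, ir3 = ir / r2;
      ax += sx[j] * ir; ay += sy[j] * ir; az += sz[j] * ir;
      bx += (sy[j] * dz - sz[j] * dy) * ir3;
      by += (sz[j] * dx - sx[j] * dz) * ir3;
      bz += (sx[j] * dy - sy[j] * dx) * ir3;
    }
    A(i, 0) = ax; A(i, 1) = ay; A(i, 2) = az;
    B(i, 0) = bx; B(i, 1) = by; B(i, 2) = bz;
  }
  return List::create(_["A"] = A, _["B"] = B);
}

// Neumann double filament sum for self-inductance (m = n terms omitted):
//   sum_m | (w_m s_m) . sum_{n != m} w_n s_n / |r_m - r_n| |
// [[Rcpp::export]]
double cpp_neumann_self(NumericMatrix mid, NumericMatrix svec, NumericVector w) {
  const int m = mid.nrow();
  std::vector<double> sx(m), sy(m), sz(m);
  for (int j = 0; j < m; ++j) {
    sx[j] = w[j] * svec(j, 0); sy[j] = w[j] * svec(j, 1); sz[j] = w[j] * svec(j, 2);
  }
  double L = 0.0;
  for (int i = 0; i < m; ++i) {
    double ix = 0, iy = 0, iz = 0;
    const double px = mid(i, 0), py = mid(i, 1), pz = mid(i, 2);
    for (int j = 0; j < m; ++j) {
      if (j == i) continue;
      const double dx = px - mid(j, 0), dy = py - mid(j, 1), dz = pz - mid(j, 2);
      const double ir = 1.0 / std::sqrt(dx * dx + dy * dy + dz * dz);
      ix += sx[j] * ir; iy += sy[j] * ir; iz += sz[j] * ir;
    }
    L += std::fabs(sx[i] * ix + sy[i] * iy + sz[i] * iz);
  }
  return L;
}

// Cross-coil Neumann sum (no absolute value; symmetric in the two coils).
// [[Rcpp::export]]
double cpp_neumann_mutual(NumericMatrix mida, NumericMatrix sveca, NumericVector wa,
                          NumericMatrix midb, NumericMatrix svecb, NumericVector wb,
                          double guard) {
  const int na = mida.nrow(), nb = midb.nrow();
  double M = 0.0;
  for (int i = 0; i < na; ++i) {
    const double px = mida(i, 0), py = mida(i, 1), pz = mida(i, 2);
    const double ax = wa[i] * sveca(i, 0), ay = wa[i] * sveca(i, 1), az = wa[i] * sveca(i, 2);
    for (int j = 0; j < nb; ++j) {
      const double dx = px - midb(j, 0), dy = py - midb(j, 1), dz = pz - midb(j, 2);
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < guard * guard)
        stop("filament %d of coil A intersects filament %d of coil B", i + 1, j + 1);
      const double ir = 1.0 / std::sqrt(r2);
      M += (ax * wb[j] * svecb(j, 0) + ay * wb[j] * svecb(j, 1) + az * wb[j] * svecb(j, 2)) * ir;
    }
  }
  return M;
}

// Analytic field integral of a constant unit surface density over a flat
// triangle:  g(p) = int_T (p - r') / |p - r'|^3 dS'.
// Decomposition: in-plane edge terms (line potentials times in-plane outward
// edge normals) plus the signed solid angle along the facet normal.  The
// observation point exactly in the triangle plane yields the principal value
// (solid-angle term dropped).
static void tri_field_analytic(const double* v1, const double* v2, const double* v3,
                               const double* p, double* g) {
  double e1[3], e2[3], nrm[3];
  for (int k = 0; k < 3; ++k) { e1[k] = v2[k] - v1[k]; e2[k] = v3[k] - v1[k]; }
  cross3(e1, e2, nrm);
  const double nn = norm3(nrm);
  for (int k = 0; k < 3; ++k) nrm[k] /= nn;
  const double scale = std::sqrt(nn);

  g[0] = g[1] = g[2] = 0.0;
  const double* vv[4] = {v1, v2, v3, v1};
  for (int e = 0; e < 3; ++e) {
    const double* a = vv[e];
    const double* b = vv[e + 1];
    double t[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
    const double lt = norm3(t);
    for (int k = 0; k < 3; ++k) t[k] /= lt;
    double mhat[3];
    cross3(t, nrm, mhat);
    double ra[3] = {a[0] - p[0], a[1] - p[1], a[2] - p[2]};
    double rb[3] = {b[0] - p[0], b[1] - p[1], b[2] - p[2]};
    const double sa = dot3(ra, t), sb = dot3(rb, t);
    const double Ra = norm3(ra), Rb = norm3(rb);
    double Lint;
    if (sa + sb >= 0.0)
      Lint = std::log((Rb + sb) / (Ra + sa));
    else
      Lint = std::log((Ra - sa) / (Rb - sb));
    if (!std::isfinite(Lint)) Lint = 0.0;  // p on the edge line: PV of the edge term
    g[0] += mhat[0] * Lint; g[1] += mhat[1] * Lint; g[2] += mhat[2] * Lint;
  }
  // signed solid angle (van Oosterom & Strackee)
  double r1[3] = {v1[0] - p[0], v1[1] - p[1], v1[2] - p[2]};
  double r2[3] = {v2[0] - p[0], v2[1] - p[1], v2[2] - p[2]};
  double r3[3] = {v3[0] - p[0], v3[1] - p[1], v3[2] - p[2]};
  const double h = -(r1[0] * nrm[0] + r1[1] * nrm[1] + r1[2] * nrm[2]);
  if (std::fabs(h) > 1e-12 * scale) {
    double c23[3];
    cross3(r2, r3, c23);
    const double det = dot3(r1, c23);
    const double R1 = norm3(r1), R2 = norm3(r2), R3 = norm3(r3);
    const double den = R1 * R2 * R3 + dot3(r1, r2) * R3 + dot3(r1, r3) * R2 +
                       dot3(r2, r3) * R1;
    // with r_i = v_i - p, the van Oosterom-Strackee angle is negative when
    // p lies on the +n side, so the outward normal term carries a minus sign
    const double omega = 2.0 * std::atan2(det, den);
    g[0] -= nrm[0] * omega; g[1] -= nrm[1] * omega; g[2] -= nrm[2] * omega;
  }
}

// Analytic potential integral of a constant unit density over a triangle:
//   I(p) = int_T 1 / |p - r'| dS'
// (edge-distance log terms minus the height times the signed solid angle).
static double tri_potential_analytic(const double* v1, const double* v2,
                                     const double* v3, const double* p) {
  double e1[3], e2[3], nrm[3];
  for (int k = 0; k < 3; ++k) { e1[k] = v2[k] - v1[k]; e2[k] = v3[k] - v1[k]; }
  cross3(e1, e2, nrm);
  const double nn = norm3(nrm);
  for (int k = 0; k < 3; ++k) nrm[k] /= nn;
  const double scale = std::sqrt(nn);
  double I = 0.0;
  const double* vv[4] = {v1, v2, v3, v1};
  for (int e = 0; e < 3; ++e) {
    const double* a = vv[e];
    const double* b = vv[e + 1];
    double t[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
    const double lt = norm3(t);
    for (int k = 0; k < 3; ++k) t[k] /= lt;
    double mhat[3];
    cross3(t, nrm, mhat);
    double ra[3] = {a[0] - p[0], a[1] - p[1], a[2] - p[2]};
    double rb[3] = {b[0] - p[0], b[1] - p[1], b[2] - p[2]};
    const double sa = dot3(ra, t), sb = dot3(rb, t);
    const double Ra = norm3(ra), Rb = norm3(rb);
    double Lint;
    if (sa + sb >= 0.0)
      Lint = std::log((Rb + sb) / (Ra + sa));
    else
      Lint = std::log((Ra - sa) / (Rb - sb));
    if (!std::isfinite(Lint)) Lint = 0.0;
    I += dot3(mhat, ra) * Lint;
  }
  double r1[3] = {v1[0] - p[0], v1[1] - p[1], v1[2] - p[2]};
  double r2[3] = {v2[0] - p[0], v2[1] - p[1], v2[2] - p[2]};
  double r3[3] = {v3[0] - p[0], v3[1] - p[1], v3[2] - p[2]};
  const double h = -(r1[0] * nrm[0] + r1[1] * nrm[1] + r1[2] * nrm[2]);
  if (std::fabs(h) > 1e-12 * scale) {
    double c23[3];
    cross3(r2, r3, c23);
    const double det = dot3(r1, c23);
    const double R1 = norm3(r1), R2 = norm3(r2), R3 = norm3(r3);
    const double den = R1 * R2 * R3 + dot3(r1, r2) * R3 + dot3(r1, r3) * R2 +
                       dot3(r2, r3) * R1;
    const double omega = -2.0 * std::atan2(det, den);  // sign(h) * |Omega|
    I -= h * omega;
  }
  return I;
}

// Single-layer potential of face charges at arbitrary points
// (analytic near integrals, centroid rule far; continuous across faces).
// [[Rcpp::export]]
NumericVector cpp_single_layer_potential(NumericMatrix V, IntegerMatrix F,
                                         NumericMatrix centers, NumericVector areas,
                                         NumericVector rho, NumericMatrix pts,
                                         double eta) {
  const int nf = F.nrow(), np = pts.nrow();
  NumericVector phi(np);
  const double fourpi = 4.0 * M_PI;
  std::vector<double> rad(nf);
  for (int j = 0; j < nf; ++j) {
    double r = 0;
    for (int t = 0; t < 3; ++t) {
      const int vi = F(j, t);
      const double dx = V(vi, 0) - centers(j, 0), dy = V(vi, 1) - centers(j, 1),
                   dz = V(vi, 2) - centers(j, 2);
      r = std::max(r, std::sqrt(dx * dx + dy * dy + dz * dz));
    }
    rad[j] = r;
  }
  for (int i = 0; i < np; ++i) {
    double p[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    double s = 0.0;
    for (int j = 0; j < nf; ++j) {
      if (rho[j] == 0.0) continue;
      const double dx = p[0] - centers(j, 0), dy = p[1] - centers(j, 1),
                   dz = p[2] - centers(j, 2);
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 <= eta * eta * rad[j] * rad[j]) {
        double v1[3], v2[3], v3[3];
        for (int k = 0; k < 3; ++k) {
          v1[k] = V(F(j, 0), k); v2[k] = V(F(j, 1), k); v3[k] = V(F(j, 2), k);
        }
        s += rho[j] * tri_potential_analytic(v1, v2, v3, p);
      } else {
        s += rho[j] * areas[j] / std::sqrt(r2);
      }
    }
    phi[i] = s / fourpi;
  }
  return phi;
}

// [[Rcpp::export]]
NumericMatrix cpp_tri_field(NumericMatrix v, NumericMatrix pts) {
  // v: 3 x 3 matrix of triangle vertices (rows); pts: n x 3
  const int n = pts.nrow();
  NumericMatrix g(n, 3);
  double v1[3], v2[3], v3[3];
  for (int k = 0; k < 3; ++k) { v1[k] = v(0, k); v2[k] = v(1, k); v3[k] = v(2, k); }
  for (int i = 0; i < n; ++i) {
    double p[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    double gi[3];
    tri_field_analytic(v1, v2, v3, p, gi);
    g(i, 0) = gi[0]; g(i, 1) = gi[1]; g(i, 2) = gi[2];
  }
  return g;
}

// Dense influence matrix for the second-kind charge equation:
//   G[i, j] = (1/4pi) n_i . int_{face j} (c_i - r') / |c_i - r'|^3 dS'
// evaluated at face centers c_i.  Faces within eta face-radii of the
// observation point use the analytic triangle integral (self entries reduce
// to the principal value, whose normal component vanishes); farther faces
// use the one-point centroid rule.
// [[Rcpp::export]]
NumericMatrix cpp_G_matrix(NumericMatrix V, IntegerMatrix F, NumericMatrix centers,
                           NumericMatrix normals, NumericVector areas, double eta) {
  const int nf = F.nrow();
  NumericMatrix G(nf, nf);
  const double fourpi = 4.0 * M_PI;
  std::vector<double> rad(nf);
  for (int j = 0; j < nf; ++j) {
    double r = 0;
    for (int t = 0; t < 3; ++t) {
      const int vi = F(j, t);
      const double dx = V(vi, 0) - centers(j, 0), dy = V(vi, 1) - centers(j, 1),
                   dz = V(vi, 2) - centers(j, 2);
      r = std::max(r, std::sqrt(dx * dx + dy * dy + dz * dz));
    }
    rad[j] = r;
  }
  for (int i = 0; i < nf; ++i) {
    const double px = centers(i, 0), py = centers(i, 1), pz = centers(i, 2);
    const double nx = normals(i, 0), ny = normals(i, 1), nz = normals(i, 2);
    double p[3] = {px, py, pz};
    for (int j = 0; j < nf; ++j) {
      const double dx = px - centers(j, 0), dy = py - centers(j, 1), dz = pz - centers(j, 2);
      const double r2 = dx * dx + dy * dy + dz * dz;
      const double near2 = eta * eta * rad[j] * rad[j];
      double val;
      if (i == j) {
        val = 0.0;  // principal value: tangential only, no normal component
      } else if (r2 <= near2) {
        double v1[3], v2[3], v3[3], g[3];
        for (int k = 0; k < 3; ++k) {
          v1[k] = V(F(j, 0), k); v2[k] = V(F(j, 1), k); v3[k] = V(F(j, 2), k);
        }
        tri_field_analytic(v1, v2, v3, p, g);
        val = nx * g[0] + ny * g[1] + nz * g[2];
      } else {
        const double ir3 = 1.0 / (r2 * std::sqrt(r2));
        val = areas[j] * (nx * dx + ny * dy + nz * dz) * ir3;
      }
      G(i, j) = val / fourpi;
    }
  }
  return G;
}

// Component-wise single-layer field matrices at fixed observation points:
//   Hx[i, j] = (1/4pi) [int_{face j} (p_i - r')/|p_i - r'|^3 dS']_x   etc.
// so that the (unscaled) secondary field is Hx %*% rho, Hy %*% rho, Hz %*% rho.
// [[Rcpp::export]]
List cpp_H_matrices(NumericMatrix V, IntegerMatrix F, NumericMatrix centers,
                    NumericVector areas, NumericMatrix pts, double eta) {
  const int nf = F.nrow(), np = pts.nrow();
  NumericMatrix Hx(np, nf), Hy(np, nf), Hz(np, nf);
  const double fourpi = 4.0 * M_PI;
  std::vector<double> rad(nf);
  for (int j = 0; j < nf; ++j) {
    double r = 0;
    for (int t = 0; t < 3; ++t) {
      const int vi = F(j, t);
      const double dx = V(vi, 0) - centers(j, 0), dy = V(vi, 1) - centers(j, 1),
                   dz = V(vi, 2) - centers(j, 2);
      r = std::max(r, std::sqrt(dx * dx + dy * dy + dz * dz));
    }
    rad[j] = r;
  }
  for (int i = 0; i < np; ++i) {
    double p[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    for (int j = 0; j < nf; ++j) {
      const double dx = p[0] - centers(j, 0), dy = p[1] - centers(j, 1),
                   dz = p[2] - centers(j, 2);
      const double r2 = dx * dx + dy * dy + dz * dz;
      double g[3];
      if (r2 <= eta * eta * rad[j] * rad[j]) {
        double v1[3], v2[3], v3[3];
        for (int k = 0; k < 3; ++k) {
          v1[k] = V(F(j, 0), k); v2[k] = V(F(j, 1), k); v3[k] = V(F(j, 2), k);
        }
        tri_field_analytic(v1, v2, v3, p, g);
      } else {
        const double ir3 = 1.0 / (r2 * std::sqrt(r2));
        g[0] = areas[j] * dx * ir3; g[1] = areas[j] * dy * ir3; g[2] = areas[j] * dz * ir3;
      }
      Hx(i, j) = g[0] / fourpi; Hy(i, j) = g[1] / fourpi; Hz(i, j) = g[2] / fourpi;
    }
  }
  return List::create(_["Hx"] = Hx, _["Hy"] = Hy, _["Hz"] = Hz);
}

// Matrix-free single-layer field of face charges rho at arbitrary points
// (principal value on any face plane).
// [[Rcpp::export]]
NumericMatrix cpp_single_layer_H(NumericMatrix V, IntegerMatrix F, NumericMatrix centers,
                                 NumericVector areas, NumericVector rho,
                                 NumericMatrix pts, double eta) {
  const int nf = F.nrow(), np = pts.nrow();
  NumericMatrix H(np, 3);
  const double fourpi = 4.0 * M_PI;
  std::vector<double> rad(nf);
  for (int j = 0; j < nf; ++j) {
    double r = 0;
    for (int t = 0; t < 3; ++t) {
      const int vi = F(j, t);
      const double dx = V(vi, 0) - centers(j, 0), dy = V(vi, 1) - centers(j, 1),
                   dz = V(vi, 2) - centers(j, 2);
      r = std::max(r, std::sqrt(dx * dx + dy * dy + dz * dz));
    }
    rad[j] = r;
  }
  for (int i = 0; i < np; ++i) {
    double p[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    double hx = 0, hy = 0, hz = 0;
    for (int j = 0; j < nf; ++j) {
      if (rho[j] == 0.0) continue;
      const double dx = p[0] - centers(j, 0), dy = p[1] - centers(j, 1),
                   dz = p[2] - centers(j, 2);
      const double r2 = dx * dx + dy * dy + dz * dz;
      double g[3];
      if (r2 <= eta * eta * rad[j] * rad[j]) {
        double v1[3], v2[3], v3[3];
        for (int k = 0; k < 3; ++k) {
          v1[k] = V(F(j, 0), k); v2[k] = V(F(j, 1), k); v3[k] = V(F(j, 2), k);
        }
        tri_field_analytic(v1, v2, v3, p, g);
      } else {
        const double ir3 = 1.0 / (r2 * std::sqrt(r2));
        g[0] = areas[j] * dx * ir3; g[1] = areas[j] * dy * ir3; g[2] = areas[j] * dz * ir3;
      }
      hx += rho[j] * g[0]; hy += rho[j] * g[1]; hz += rho[j] * g[2];
    }
    H(i, 0) = hx / fourpi; H(i, 1) = hy / fourpi; H(i, 2) = hz / fourpi;
  }
  return H;
}

// Secondary vector potential of the magnetized core (unscaled):
//   sum_t V_t M_t x (p - r_t) / |p - r_t|^3
// Near points (within eta tet-radii of the centroid) use Bey's one-level
// red refinement into 8 children instead of the centroid rule.
// [[Rcpp::export]]
NumericMatrix cpp_As_from_M(NumericMatrix tv, NumericVector vol, NumericMatrix M,
                            NumericMatrix pts, double eta) {
  // tv: nt x 12 (the four vertices of each tet, xyz interleaved by vertex)
  const int nt = tv.nrow(), np = pts.nrow();
  NumericMatrix A(np, 3);
  std::vector<double> cx(nt), cy(nt), cz(nt), rad(nt);
  for (int t = 0; t < nt; ++t) {
    cx[t] = 0.25 * (tv(t, 0) + tv(t, 3) + tv(t, 6) + tv(t, 9));
    cy[t] = 0.25 * (tv(t, 1) + tv(t, 4) + tv(t, 7) + tv(t, 10));
    cz[t] = 0.25 * (tv(t, 2) + tv(t, 5) + tv(t, 8) + tv(t, 11));
    double r = 0;
    for (int k = 0; k < 4; ++k) {
      const double dx = tv(t, 3 * k) - cx[t], dy = tv(t, 3 * k + 1) - cy[t],
                   dz = tv(t, 3 * k + 2) - cz[t];
      r = std::max(r, std::sqrt(dx * dx + dy * dy + dz * dz));
    }
    rad[t] = r;
  }
  // Bey red-refinement children in barycentric vertex-pair notation
  const int child[8][4][2] = {
      {{0, 0}, {0, 1}, {0, 2}, {0, 3}}, {{0, 1}, {1, 1}, {1, 2}, {1, 3}},
      {{0, 2}, {1, 2}, {2, 2}, {2, 3}}, {{0, 3}, {1, 3}, {2, 3}, {3, 3}},
      {{0, 1}, {0, 2}, {0, 3}, {1, 3}}, {{0, 1}, {0, 2}, {1, 2}, {1, 3}},
      {{0, 2}, {0, 3}, {1, 3}, {2, 3}}, {{0, 2}, {1, 2}, {1, 3}, {2, 3}}};
  for (int i = 0; i < np; ++i) {
    const double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    double ax = 0, ay = 0, az = 0;
    for (int t = 0; t < nt; ++t) {
      const double mx = M(t, 0), my = M(t, 1), mz = M(t, 2);
      if (mx == 0 && my == 0 && mz == 0) continue;
      double dx = px - cx[t], dy = py - cy[t], dz = pz - cz[t];
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > eta * eta * rad[t] * rad[t]) {
        const double ir3 = vol[t] / (r2 * std::sqrt(r2));
        ax += (my * dz - mz * dy) * ir3;
        ay += (mz * dx - mx * dz) * ir3;
        az += (mx * dy - my * dx) * ir3;
      } else {
        for (int c = 0; c < 8; ++c) {
          double gx = 0, gy = 0, gz = 0;
          for (int k = 0; k < 4; ++k) {
            const int a = child[c][k][0], b = child[c][k][1];
            gx += 0.5 * (tv(t, 3 * a) + tv(t, 3 * b));
            gy += 0.5 * (tv(t, 3 * a + 1) + tv(t, 3 * b + 1));
            gz += 0.5 * (tv(t, 3 * a + 2) + tv(t, 3 * b + 2));
          }
          gx *= 0.25; gy *= 0.25; gz *= 0.25;
          dx = px - gx; dy = py - gy; dz = pz - gz;
          const double rr2 = dx * dx + dy * dy + dz * dz;
          if (rr2 == 0.0) continue;
          const double ir3 = 0.125 * vol[t] / (rr2 * std::sqrt(rr2));
          ax += (my * dz - mz * dy) * ir3;
          ay += (mz * dx - mx * dz) * ir3;
          az += (mx * dy - my * dx) * ir3;
        }
      }
    }
    A(i, 0) = ax; A(i, 1) = ay; A(i, 2) = az;
  }
  return A;
}

// Ray-casting point-in-closed-surface test (Moller-Trumbore, fixed skew ray
// direction to avoid edge/vertex degeneracies on structured meshes).
// [[Rcpp::export]]
LogicalVector cpp_points_in_surface(NumericMatrix V, IntegerMatrix F, NumericMatrix pts) {
  const int nf = F.nrow(), np = pts.nrow();
  double d[3] = {0.577350269, 0.544331054, 0.608580619};
  const double dn = norm3(d);
  for (int k = 0; k < 3; ++k) d[k] /= dn;
  LogicalVector inside(np);
  for (int i = 0; i < np; ++i) {
    const double o[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    int crossings = 0;
    for (int j = 0; j < nf; ++j) {
      double v0[3], e1[3], e2[3];
      for (int k = 0; k < 3; ++k) {
        v0[k] = V(F(j, 0), k);
        e1[k] = V(F(j, 1), k) - v0[k];
        e2[k] = V(F(j, 2), k) - v0[k];
      }
      double pv[3];
      cross3(d, e2, pv);
      const double det = dot3(e1, pv);
      if (std::fabs(det) < 1e-14) continue;
      const double inv = 1.0 / det;
      double tvec[3] = {o[0] - v0[0], o[1] - v0[1], o[2] - v0[2]};
      const double u = dot3(tvec, pv) * inv;
      if (u < 0.0 || u > 1.0) continue;
      double qv[3];
      cross3(tvec, e1, qv);
      const double vv = dot3(d, qv) * inv;
      if (vv < 0.0 || u + vv > 1.0) continue;
      const double tt = dot3(e2, qv) * inv;
      if (tt > 1e-12) ++crossings;
    }
    inside[i] = (crossings % 2) == 1;
  }
  return inside;
}
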