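// Numeric kernels: Siddon-style ray traversal for the divergent-beam dose
// engine and corner-projection/convex-hull rasterization of 3D masks into
// the BEV plane. Geometry conventions match R/geometry.R: M's columns are
// the BCS axes in DCS, the source sits at iso + SAD * M[,1].

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Radiological path length (mm * relative density) from s to p through an
// axis-aligned isotropic grid (Amanatides & Woo incremental traversal).
// Voxel extents are half-open boxes of side sp centred on lattice points.
static double radiological_path(const double* dens, const int* n,
                                const double* bmin, double sp,
                                const double s[3], const double p[3]) {
  double dir[3] = {p[0] - s[0], p[1] - s[1], p[2] - s[2]};
  double len = std::sqrt(dir[0]*dir[0] + dir[1]*dir[1] + dir[2]*dir[2]);
  if (len <= 0.0) return 0.0;

  double t0 = 0.0, t1 = 1.0;
  for (int ax = 0; ax < 3; ++ax) {
    double bmax = bmin[ax] + n[ax] * sp;
    if (std::fabs(dir[ax]) < 1e-12) {
      if (s[ax] <= bmin[ax] || s[ax] >= bmax) return 0.0;
    } else {
      double ta = (bmin[ax] - s[ax]) / dir[ax];
      double tb = (bmax - s[ax]) / dir[ax];
      if (ta > tb) std::swap(ta, tb);
      t0 = std::max(t0, ta);
      t1 = std::min(t1, tb);
    }
  }
  if (t0 >= t1) return 0.0;

  int idx[3], step[3];
  double tnext[3], tdelta[3];
  for (int ax = 0; ax < 3; ++ax) {
    double pos = s[ax] + (t0 + 1e-12) * dir[ax];
    idx[ax] = (int)std::floor((pos - bmin[ax]) / sp);
    idx[ax] = std::max(0, std::min(n[ax] - 1, idx[ax]));
    if (dir[ax] > 1e-12) {
      step[ax] = 1;
      tdelta[ax] = sp / dir[ax];
      tnext[ax] = (bmin[ax] + (idx[ax] + 1) * sp - s[ax]) / dir[ax];
    } else if (dir[ax] < -1e-12) {
      step[ax] = -1;
      tdelta[ax] = -sp / dir[ax];
      tnext[ax] = (bmin[ax] + idx[ax] * sp - s[ax]) / dir[ax];
    } else {
      step[ax] = 0;
      tdelta[ax] = tnext[ax] = R_PosInf;
    }
  }

  double acc = 0.0, t = t0;
  while (t < t1 - 1e-12) {
    int ax = 0;
    if (tnext[1] < tnext[ax]) ax = 1;
    if (tnext[2] < tnext[ax]) ax = 2;
    double tstop = std::min(tnext[ax], t1);
    double rho = dens[idx[0] + (size_t)n[0] * (idx[1] + (size_t)n[1] * idx[2])];
    if (rho > 0.0) acc += rho * (tstop - t) * len;
    t = tstop;
    if (tnext[ax] >= t1) break;
    idx[ax] += step[ax];
    if (idx[ax] < 0 || idx[ax] >= n[ax]) break;
    tnext[ax] += tdelta[ax];
  }
  return acc;
}

// leaf pair index for zb, or -1 when outside the bank
static int pair_index(const NumericVector& bnd, double zb) {
  int np = bnd.size() - 1;
  if (zb < bnd[0] || zb >= bnd[np]) return -1;
  int lo = 0, hi = np;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (zb >= bnd[mid]) lo = mid; else hi = mid;
  }
  return lo;
}

static bool aperture_open(double xb, double zb, const NumericVector& jaw,
                          const NumericVector& bnd, const NumericVector& x1,
                          const NumericVector& x2) {
  if (xb <= jaw[0] || xb >= jaw[1] || zb <= jaw[2] || zb >= jaw[3]) return false;
  int k = pair_index(bnd, zb);
  if (k < 0) return false;
  return xb > x1[k] && xb < x2[k];
}

// [[Rcpp::export]]
NumericVector cpp_beam_dose(NumericVector density, IntegerVector dims,
                            NumericVector origin, double spacing,
                            NumericMatrix M, NumericVector iso, double sad,
                            NumericVector jaw, NumericVector bnd,
                            NumericVector x1, NumericVector x2,
                            double t_mlc, double mu, bool inv_square) {
  int n[3] = {dims[0], dims[1], dims[2]};
  double bmin[3] = {origin[0] - 0.5 * spacing, origin[1] - 0.5 * spacing,
                    origin[2] - 0.5 * spacing};
  // source at iso + sad * Y' axis
  double src[3] = {iso[0] + sad * M(0, 1), iso[1] + sad * M(1, 1),
                   iso[2] + sad * M(2, 1)};
  const double* dens = density.begin();
  NumericVector out((size_t)n[0] * n[1] * n[2]);

  size_t v = 0;
  for (int k = 0; k < n[2]; ++k) {
    double pz = origin[2] + k * spacing;
    for (int j = 0; j < n[1]; ++j) {
      double py = origin[1] + j * spacing;
      for (int i = 0; i < n[0]; ++i, ++v) {
        if (dens[v] <= 0.0) continue;          // outside the patient
        double px = origin[0] + i * spacing;
        double q[3] = {px - iso[0], py - iso[1], pz - iso[2]};
        double Xp = q[0] * M(0, 0) + q[1] * M(1, 0) + q[2] * M(2, 0);
        double Yp = q[0] * M(0, 1) + q[1] * M(1, 1) + q[2] * M(2, 1);
        double Zp = q[0] * M(0, 2) + q[1] * M(1, 2) + q[2] * M(2, 2);
        if (Yp >= sad - 1e-6)
          stop("voxel at or beyond the source plane (Y' >= SAD)");
        double mag = sad / (sad - Yp);
        double A = aperture_open(Xp * mag, Zp * mag, jaw, bnd, x1, x2)
                     ? 1.0 : t_mlc;
        if (A == 0.0) continue;
        double pt[3] = {px, py, pz};
        double ell = radiological_path(dens, n, bmin, spacing, src, pt);
        double d = A * std::exp(-mu * ell);
        if (inv_square) {
          double dx = px - src[0], dy = py - src[1], dz = pz - src[2];
          d *= sad * sad / (dx * dx + dy * dy + dz * dz);
        }
        out[v] = d;
      }
    }
  }
  return out;
}

// --- convex hull helpers (Andrew monotone chain) ---

struct Pt { double x, z; };

static double cross(const Pt& o, const Pt& a, const Pt& b) {
  return (a.x - o.x) * (b.z - o.z) - (a.z - o.z) * (b.x - o.x);
}

static std::vector<Pt> convex_hull(std::vector<Pt> pts) {
  std::sort(pts.begin(), pts.end(), [](const Pt& a, const Pt& b) {
    return a.x < b.x || (a.x == b.x && a.z < b.z);
  });
  pts.erase(std::unique(pts.begin(), pts.end(), [](const Pt& a, const Pt& b) {
    return a.x == b.x && a.z == b.z;
  }), pts.end());
  int m = pts.size();
  if (m < 3) return pts;
  std::vector<Pt> h(2 * m);
  int k = 0;
  for (int i = 0; i < m; ++i) {               // lower hull
    while (k >= 2 && cross(h[k - 2], h[k - 1], pts[i]) <= 0) --k;
    h[k++] = pts[i];
  }
  for (int i = m - 2, t = k + 1; i >= 0; --i) { // upper hull
    while (k >= t && cross(h[k - 2], h[k - 1], pts[i]) <= 0) --k;
    h[k++] = pts[i];
  }
  h.resize(k - 1);
  return h;
}

// point-in-convex-polygon (CCW hull, boundary counts as inside)
static bool in_hull(const std::vector<Pt>& h, double x, double z) {
  int m = h.size();
  if (m == 1) return std::fabs(x - h[0].x) < 1e-9 && std::fabs(z - h[0].z) < 1e-9;
  if (m == 2) {
    Pt p{x, z};
    if (std::fabs(cross(h[0], h[1], p)) > 1e-9) return false;
    double t = (h[1].x - h[0].x) * (x - h[0].x) + (h[1].z - h[0].z) * (z - h[0].z);
    double l2 = (h[1].x - h[0].x) * (h[1].x - h[0].x) +
                (h[1].z - h[0].z) * (h[1].z - h[0].z);
    return t >= -1e-9 && t <= l2 + 1e-9;
  }
  Pt p{x, z};
  for (int i = 0; i < m; ++i)
    if (cross(h[i], h[(i + 1) % m], p) < -1e-9) return false;
  return true;
}

// [[Rcpp::export]]
LogicalMatrix cpp_project_mask_bev(IntegerMatrix vox, NumericVector origin,
                                   double spacing, NumericMatrix M,
                                   NumericVector iso, double sad,
                                   double xmin, double zmin, double pixel,
                                   int nx, int nz) {
  LogicalMatrix out(nx, nz);
  double h = 0.5 * spacing;
  const double cs[2] = {-h, h};
  for (int r = 0; r < vox.nrow(); ++r) {
    double cx = origin[0] + vox(r, 0) * spacing;
    double cy = origin[1] + vox(r, 1) * spacing;
    double cz = origin[2] + vox(r, 2) * spacing;
    std::vector<Pt> pts;
    pts.reserve(8);
    for (int a = 0; a < 2; ++a)
      for (int b = 0; b < 2; ++b)
        for (int c = 0; c < 2; ++c) {
          double q[3] = {cx + cs[a] - iso[0], cy + cs[b] - iso[1],
                         cz + cs[c] - iso[2]};
          double Xp = q[0] * M(0, 0) + q[1] * M(1, 0) + q[2] * M(2, 0);
          double Yp = q[0] * M(0, 1) + q[1] * M(1, 1) + q[2] * M(2, 1);
          double Zp = q[0] * M(0, 2) + q[1] * M(1, 2) + q[2] * M(2, 2);
          if (Yp >= sad - 1e-6)
            stop("mask voxel at or beyond the source plane (Y' >= SAD)");
          double mag = sad / (sad - Yp);
          pts.push_back(Pt{Xp * mag, Zp * mag});
        }
    std::vector<Pt> hull = convex_hull(pts);
    double bx0 = pts[0].x, bx1 = pts[0].x, bz0 = pts[0].z, bz1 = pts[0].z;
    for (const Pt& p : pts) {
      bx0 = std::min(bx0, p.x); bx1 = std::max(bx1, p.x);
      bz0 = std::min(bz0, p.z); bz1 = std::max(bz1, p.z);
    }
    int i0 = std::max(0, (int)std::floor((bx0 - xmin) / pixel - 0.5));
    int i1 = std::min(nx - 1, (int)std::ceil((bx1 - xmin) / pixel - 0.5));
    int j0 = std::max(0, (int)std::floor((bz0 - zmin) / pixel - 0.5));
    int j1 = std::min(nz - 1, (int)std::ceil((bz1 - zmin) / pixel - 0.5));
    for (int j = j0; j <= j1; ++j) {
      double zc = zmin + (j + 0.5) * pixel;
      for (int i = i0; i <= i1; ++i) {
        if (out(i, j)) continue;
        double xc = xmin + (i + 0.5) * pixel;
        if (in_hull(hull, xc, zc)) out(i, j) = true;
      }
    }
  }
  return out;
}
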