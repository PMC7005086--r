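// Maugis-Dugdale contact narrow phase: triangle-pair projection, polygon
// clipping and Gauss quadrature of the adhesive + Hertz traction field.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct V3 { double x, y, z; };
static inline V3 v3(double x, double y, double z) { V3 v = {x, y, z}; return v; }
static inline V3 operator-(V3 a, V3 b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline V3 operator+(V3 a, V3 b) { return v3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline V3 operator*(V3 a, double s) { return v3(a.x * s, a.y * s, a.z * s); }
static inline double dot(V3 a, V3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline V3 cross(V3 a, V3 b) {
  return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double norm(V3 a) { return std::sqrt(dot(a, a)); }

// ---- Maugis m = c/a ---------------------------------------------------------
// g(m) = (lambda/2) A^(2/3) [(m^2-2) asec(m) + sqrt(m^2-1)]
//      + (4 lambda^2/3) A^(1/3) [sqrt(m^2-1) asec(m) - m + 1]  == 1
// with A = 4 a^3 Ehat / (3 pi W Rhat^2); asec(m) = atan(sqrt(m^2-1)).
static double maugis_g(double m, double lambda, double A) {
  double s = std::sqrt(std::max(m * m - 1.0, 0.0));
  double as = std::atan(s);
  double A13 = std::cbrt(A);
  return 0.5 * lambda * A13 * A13 * ((m * m - 2.0) * as + s) +
         (4.0 / 3.0) * lambda * lambda * A13 * (s * as - m + 1.0);
}

static double maugis_m(double lambda, double A, bool *ok) {
  *ok = true;
  double lo = 1.0 + 1e-12, hi = 2.0;
  double glo = maugis_g(lo, lambda, A) - 1.0;
  if (glo > 0) { *ok = false; return 1.0; }
  double ghi = maugis_g(hi, lambda, A) - 1.0;
  int guard = 0;
  while (ghi < 0 && guard++ < 60) { hi *= 2.0; ghi = maugis_g(hi, lambda, A) - 1.0; }
  if (ghi < 0) { *ok = false; return 1.0; }
  for (int it = 0; it < 200; ++it) {
    double mid = 0.5 * (lo + hi);
    double g = maugis_g(mid, lambda, A) - 1.0;
    if (std::fabs(g) < 1e-10 && (hi - lo) < 1e-9 * mid) return mid;
    if (g < 0) lo = mid; else hi = mid;
  }
  return 0.5 * (lo + hi);
}

// [[Rcpp::export]]
double cpp_maugis_m(double lambda, double A) {
  bool ok;
  double m = maugis_m(lambda, A, &ok);
  return ok ? m : NA_REAL;
}

// ---- traction ---------------------------------------------------------------
static inline double traction(double r, double a, double c, double sigma0,
                              double Ehat, double Rhat, bool adhesion) {
  double p = 0.0;
  if (r < a) {
    p += 2.0 * Ehat / (M_PI * Rhat) * std::sqrt(std::max(a * a - r * r, 0.0));
    if (adhesion && c > a) {
      double den = c * c - r * r;
      double arg = (2.0 * a * a - c * c - r * r) / den;
      arg = std::max(-1.0, std::min(1.0, arg));
      p -= sigma0 / M_PI * std::acos(arg);
    } else if (adhesion) {
      p -= sigma0;  // c == a limit: rim value
    }
  } else if (adhesion && r <= c) {
    p -= sigma0;
  }
  return p;
}

// [[Rcpp::export]]
NumericVector cpp_md_traction(NumericVector r, double a, double c,
                              double sigma0, double Ehat, double Rhat,
                              bool adhesion) {
  NumericVector out(r.size());
  for (int i = 0; i < r.size(); ++i)
    out[i] = traction(r[i], a, c, sigma0, Ehat, Rhat, adhesion);
  return out;
}

// ---- 2D polygon helpers -----------------------------------------------------
struct P2 { double x, y; };
static inline double cross2(P2 o, P2 a, P2 b) {
  return (a.x - o.x) * (b.y - o.y) - (a.y - o.y) * (b.x - o.x);
}

static double poly_area(const std::vector<P2> &p) {
  double a = 0.0; int n = p.size();
  for (int i = 0; i < n; ++i) {
    int j = (i + 1) % n;
    a += p[i].x * p[j].y - p[j].x * p[i].y;
  }
  return 0.5 * a;
}

// Sutherland-Hodgman: clip subject polygon by convex CCW clip polygon
static std::vector<P2> clip_poly(std::vector<P2> subject, const std::vector<P2> &clip) {
  int nc = clip.size();
  for (int e = 0; e < nc && !subject.empty(); ++e) {
    P2 A = clip[e], B = clip[(e + 1) % nc];
    std::vector<P2> out;
    int n = subject.size();
    for (int i = 0; i < n; ++i) {
      P2 P = subject[i], Q = subject[(i + 1) % n];
      double dP = cross2(A, B, P), dQ = cross2(A, B, Q);
      bool inP = dP >= 0, inQ = dQ >= 0;
      if (inP) out.push_back(P);
      if (inP != inQ) {
        double t = dP / (dP - dQ);
        P2 X = { P.x + t * (Q.x - P.x), P.y + t * (Q.y - P.y) };
        out.push_back(X);
      }
    }
    subject = out;
  }
  return subject;
}

// affine height interpolation over a projected triangle: heights h[3] at the
// projected vertices tv[3]; returns the plane height at 2D point q
struct HPlane {
  // h(q) = h0 + gx*x + gy*y
  double h0, gx, gy;
  double at(P2 q) const { return h0 + gx * q.x + gy * q.y; }
};

static HPlane height_plane(const std::vector<P2> &tv, const double h[3]) {
  double x1 = tv[0].x, y1 = tv[0].y, x2 = tv[1].x, y2 = tv[1].y,
         x3 = tv[2].x, y3 = tv[2].y;
  double det = (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1);
  HPlane p = {h[0], 0.0, 0.0};
  if (std::fabs(det) < 1e-300) { p.h0 = (h[0] + h[1] + h[2]) / 3; return p; }
  p.gx = ((h[1] - h[0]) * (y3 - y1) - (h[2] - h[0]) * (y2 - y1)) / det;
  p.gy = ((h[2] - h[0]) * (x2 - x1) - (h[1] - h[0]) * (x3 - x1)) / det;
  p.h0 = h[0] - p.gx * x1 - p.gy * y1;
  return p;
}

// integrate traction over polygon (2D coords centered on the contact axis):
// centroid fan + 3-point mid-edge Gauss rule per sub-triangle (degree 2).
// The cohesive (Dugdale) traction acts only where the actual local surface
// separation gap(q) = hB(q) - hA(q) is within the adhesive range h0, and the
// repulsive Hertz part only under true local overlap (gap <= 0); this keeps
// the discrete tractions local even where the curvature spheres are large.
static double integrate_poly(const std::vector<P2> &poly, double a, double c,
                             double sigma0, double Ehat, double Rhat,
                             bool adhesion, double h0,
                             const HPlane &hA, const HPlane &hB,
                             int bmode, double Lb, double Rb,
                             double pen_stiff, double *area_out,
                             double *gmin_out) {
  int n = poly.size();
  double F = 0.0, A = 0.0, gmin = 1e30;
  *gmin_out = gmin;
  if (n < 3) { *area_out = 0.0; return 0.0; }
  P2 ctr = {0.0, 0.0};
  for (int i = 0; i < n; ++i) { ctr.x += poly[i].x; ctr.y += poly[i].y; }
  ctr.x /= n; ctr.y /= n;
  for (int i = 0; i < n; ++i) {
    P2 p1 = poly[i], p2 = poly[(i + 1) % n];
    double at = 0.5 * std::fabs((p1.x - ctr.x) * (p2.y - ctr.y) -
                                (p2.x - ctr.x) * (p1.y - ctr.y));
    if (at <= 0) continue;
    A += at;
    P2 q[3] = { { 0.5 * (ctr.x + p1.x), 0.5 * (ctr.y + p1.y) },
                { 0.5 * (p1.x + p2.x), 0.5 * (p1.y + p2.y) },
                { 0.5 * (p2.x + ctr.x), 0.5 * (p2.y + ctr.y) } };
    for (int k = 0; k < 3; ++k) {
      double r = std::sqrt(q[k].x * q[k].x + q[k].y * q[k].y);
      double hb = (bmode == 1)
        ? (r < Rb ? Lb - std::sqrt(Rb * Rb - r * r) : 1e30)
        : hB.at(q[k]);
      double gap = hb - hA.at(q[k]);
      if (gap < gmin) gmin = gap;
      double p = 0.0;
      if (gap <= 0.0) {
        if (r < a)
          p += 2.0 * Ehat / (M_PI * Rhat) * std::sqrt(std::max(a * a - r * r, 0.0));
        // conformal-contact penalty: flattened contacts transmit pressure
        // beyond the sphere-pair Hertz cap in proportion to local overlap
        p += pen_stiff * Ehat / h0 * (-gap);
      }
      if (adhesion && gap <= h0) {
        if (r < a && c > a) {
          double den = c * c - r * r;
          double arg = (2.0 * a * a - c * c - r * r) / den;
          arg = std::max(-1.0, std::min(1.0, arg));
          p -= sigma0 / M_PI * std::acos(arg);
        } else {
          // Dugdale cohesive zone: surfaces within the adhesive range
          p -= sigma0;
        }
      }
      F += (at / 3.0) * p;
    }
  }
  *area_out = A;
  *gmin_out = gmin;
  return F;
}

// ---- per-triangle sphere geometry -------------------------------------------
static void tri_sphere(const NumericMatrix &V, const IntegerMatrix &Tri,
                       const NumericVector &Rtri, int t,
                       V3 *bary, V3 *nrm, V3 *cen, V3 pts[3], double *R) {
  for (int k = 0; k < 3; ++k) {
    int id = Tri(t, k) - 1;
    pts[k] = v3(V(id, 0), V(id, 1), V(id, 2));
  }
  *bary = (pts[0] + pts[1] + pts[2]) * (1.0 / 3.0);
  V3 n = cross(pts[1] - pts[0], pts[2] - pts[0]);
  double nn = norm(n);
  *nrm = nn > 0 ? n * (1.0 / nn) : v3(0, 0, 1);
  *R = Rtri[t];
  *cen = *bary - (*nrm) * (*R);
}

static void plane_basis(V3 u, V3 *e1, V3 *e2) {
  V3 t = std::fabs(u.x) < 0.9 ? v3(1, 0, 0) : v3(0, 1, 0);
  V3 a = cross(u, t); a = a * (1.0 / norm(a));
  *e1 = a;
  *e2 = cross(u, a);
}

static std::vector<P2> project_tri(V3 pts[3], V3 xp, V3 u, V3 e1, V3 e2,
                                   double hout[3]) {
  std::vector<P2> poly(3);
  for (int k = 0; k < 3; ++k) {
    V3 d = pts[k] - xp;
    double h = dot(d, u);
    V3 q = d - u * h;
    poly[k].x = dot(q, e1);
    poly[k].y = dot(q, e2);
    hout[k] = h;
  }
  if (poly_area(poly) < 0) { std::swap(poly[1], poly[2]); std::swap(hout[1], hout[2]); }
  return poly;
}

// ---- cell-cell contact ------------------------------------------------------
// pairs: candidate triangle index pairs (1-based). Returns nodal forces on
// both cells, per-node contact areas, and per-patch diagnostics.
// [[Rcpp::export]]
List cpp_pair_contact(NumericMatrix V1, IntegerMatrix Tri1, NumericVector Rtri1,
                      NumericMatrix V2, IntegerMatrix Tri2, NumericVector Rtri2,
                      IntegerMatrix pairs, double sigma0, double h0, double W,
                      double Ehat, double pen_stiff) {
  int n1 = V1.nrow(), n2 = V2.nrow(), np = pairs.nrow();
  bool adhesion = (W > 0.0) && (sigma0 > 0.0);
  NumericMatrix F1(n1, 3), F2(n2, 3);
  NumericVector A1(n1), A2(n2);
  std::vector<double> diag;  // t1,t2,a,c,lambda,Fn,Aclip,delta per patch
  double tot[3] = {0, 0, 0};
  for (int p = 0; p < np; ++p) {
    int t1 = pairs(p, 0) - 1, t2 = pairs(p, 1) - 1;
    V3 b1, nA, c1, ptsA[3], b2, nB, c2, ptsB[3];
    double R1, R2;
    tri_sphere(V1, Tri1, Rtri1, t1, &b1, &nA, &c1, ptsA, &R1);
    tri_sphere(V2, Tri2, Rtri2, t2, &b2, &nB, &c2, ptsB, &R2);
    if (dot(nA, nB) >= 0.0) continue;   // only opposing surface patches
    V3 du = c2 - c1;
    double d = norm(du);
    if (d <= 0) continue;
    V3 u = du * (1.0 / d);
    if (dot(u, nA) <= 0.0) u = u * (-1.0);  // axis from A toward B
    double delta = R1 + R2 - d;
    // no sphere-level gap cut here: tractions are gated pointwise on the
    // actual inter-surface separation inside the quadrature
    double Rhat = R1 * R2 / (R1 + R2);
    double a = delta > 0 ? std::sqrt(delta * Rhat) : 0.0;
    double c = a, lambda = NA_REAL;
    if (adhesion) {
      if (a > 0) {
        lambda = sigma0 * std::cbrt(9.0 * Rhat / (2.0 * M_PI * W * Ehat * Ehat));
        double Aa = 4.0 * a * a * a * Ehat / (3.0 * M_PI * W * Rhat * Rhat);
        bool ok;
        double m = maugis_m(lambda, Aa, &ok);
        c = ok ? m * a : a;
        double cg = std::sqrt(2.0 * Rhat * (h0 + delta));
        if (!ok && cg > c) c = cg;
      } else {
        c = std::sqrt(std::max(2.0 * Rhat * (h0 + delta), 0.0));
      }
    } else if (a <= 0) {
      continue;  // no repulsion and no adhesion
    }
    // contact plane through mid-gap point, normal u
    V3 xp = c1 + u * (R1 + 0.5 * (d - R1 - R2));
    V3 e1, e2;
    plane_basis(u, &e1, &e2);
    double hAv[3], hBv[3];
    std::vector<P2> pA = project_tri(ptsA, xp, u, e1, e2, hAv);
    std::vector<P2> pB = project_tri(ptsB, xp, u, e1, e2, hBv);
    std::vector<P2> ov = clip_poly(pA, pB);
    if (ov.size() < 3) continue;
    HPlane HA = height_plane(pA, hAv), HB = height_plane(pB, hBv);
    double Aclip, gmin;
    double Fn = integrate_poly(ov, a, c, sigma0, Ehat, Rhat, adhesion, h0,
                               HA, HB, 0, 0.0, 0.0, pen_stiff, &Aclip, &gmin);
    double reach = adhesion ? h0 : 0.0;
    if (Aclip <= 0 || gmin > reach) continue;  // no actual contact here
    // Fn > 0 repulsive: push cell 1 along -u, cell 2 along +u
    double fx = -Fn * u.x, fy = -Fn * u.y, fz = -Fn * u.z;
    for (int k = 0; k < 3; ++k) {
      int i1 = Tri1(t1, k) - 1, i2 = Tri2(t2, k) - 1;
      F1(i1, 0) += fx / 3.0; F1(i1, 1) += fy / 3.0; F1(i1, 2) += fz / 3.0;
      F2(i2, 0) -= fx / 3.0; F2(i2, 1) -= fy / 3.0; F2(i2, 2) -= fz / 3.0;
      A1[i1] += Aclip / 3.0; A2[i2] += Aclip / 3.0;
    }
    tot[0] += fx; tot[1] += fy; tot[2] += fz;
    diag.push_back(t1 + 1); diag.push_back(t2 + 1);
    diag.push_back(a); diag.push_back(c); diag.push_back(lambda);
    diag.push_back(Fn); diag.push_back(Aclip); diag.push_back(delta);
    diag.push_back(gmin);
  }
  int npatch = diag.size() / 9;
  NumericMatrix patches(npatch, 9);
  for (int i = 0; i < npatch; ++i)
    for (int j = 0; j < 9; ++j) patches(i, j) = diag[9 * i + j];
  colnames(patches) = CharacterVector::create("t1", "t2", "a", "c", "lambda",
                                              "Fn", "area", "delta", "gmin");
  return List::create(_["F1"] = F1, _["F2"] = F2, _["area1"] = A1,
                      _["area2"] = A2, _["total1"] =
                        NumericVector::create(tot[0], tot[1], tot[2]),
                      _["patches"] = patches);
}

// ---- cell-smooth body contact -----------------------------------------------
// body_type 0: sphere (bx,by,bz,bR); 1: plane (point bx..bz, unit normal
// nx..nz pointing toward the cell). Returns nodal forces on the cell and the
// total reaction force on the body.
// [[Rcpp::export]]
List cpp_body_contact(NumericMatrix V, IntegerMatrix Tri, NumericVector Rtri,
                      IntegerVector tris, int body_type,
                      double bx, double by, double bz, double bR,
                      double nx, double ny, double nz,
                      double sigma0, double h0, double W, double Ehat,
                      double pen_stiff) {
  int n = V.nrow(), nt = tris.size();
  bool adhesion = (W > 0.0) && (sigma0 > 0.0);
  NumericMatrix F(n, 3);
  NumericVector A(n);
  double tot[3] = {0, 0, 0};
  std::vector<double> diag;
  for (int q = 0; q < nt; ++q) {
    int t = tris[q] - 1;
    V3 b1, nA, c1, pts[3];
    double R1;
    tri_sphere(V, Tri, Rtri, t, &b1, &nA, &c1, pts, &R1);
    V3 u;            // from cell sphere toward body
    double delta, Rhat;
    V3 xp;
    if (body_type == 0) {
      V3 cb = v3(bx, by, bz);
      V3 du = cb - c1;
      double d = norm(du);
      if (d <= 0) continue;
      u = du * (1.0 / d);
      delta = R1 + bR - d;
      Rhat = R1 * bR / (R1 + bR);
      xp = c1 + u * (R1 + 0.5 * (d - R1 - bR));
    } else {
      V3 npl = v3(nx, ny, nz);
      double s = dot(c1 - v3(bx, by, bz), npl);  // center height above plane
      if (s <= 0) continue;                       // behind the plane
      u = npl * (-1.0);
      delta = R1 - s;
      Rhat = R1;
      xp = c1 + u * (R1 + 0.5 * (s - R1));
    }
    double gap = -delta;
    if (gap > h0) continue;
    if (dot(nA, u) <= 0.0) continue;
    double a = delta > 0 ? std::sqrt(delta * Rhat) : 0.0;
    double c = a, lambda = NA_REAL;
    if (adhesion) {
      if (a > 0) {
        lambda = sigma0 * std::cbrt(9.0 * Rhat / (2.0 * M_PI * W * Ehat * Ehat));
        double Aa = 4.0 * a * a * a * Ehat / (3.0 * M_PI * W * Rhat * Rhat);
        bool ok;
        double m = maugis_m(lambda, Aa, &ok);
        c = ok ? m * a : a;
        double cg = std::sqrt(2.0 * Rhat * (h0 + delta));
        if (!ok && cg > c) c = cg;
      } else {
        c = std::sqrt(std::max(2.0 * Rhat * (h0 + delta), 0.0));
      }
    } else if (a <= 0) {
      continue;
    }
    V3 e1, e2;
    plane_basis(u, &e1, &e2);
    double hAv[3];
    std::vector<P2> pA = project_tri(pts, xp, u, e1, e2, hAv);
    HPlane HA = height_plane(pA, hAv);
    double Aclip, Fn, gmin;
    if (body_type == 0) {
      V3 cb = v3(bx, by, bz);
      double Lb = dot(cb - xp, u);
      Fn = integrate_poly(pA, a, c, sigma0, Ehat, Rhat, adhesion, h0,
                          HA, HA, 1, Lb, bR, pen_stiff, &Aclip, &gmin);
    } else {
      // plane body: constant surface height along u
      HPlane HB = {dot(v3(bx, by, bz) - xp, u), 0.0, 0.0};
      Fn = integrate_poly(pA, a, c, sigma0, Ehat, Rhat, adhesion, h0,
                          HA, HB, 0, 0.0, 0.0, pen_stiff, &Aclip, &gmin);
    }
    if (Aclip <= 0) continue;
    double fx = -Fn * u.x, fy = -Fn * u.y, fz = -Fn * u.z;
    for (int k = 0; k < 3; ++k) {
      int i1 = Tri(t, k) - 1;
      F(i1, 0) += fx / 3.0; F(i1, 1) += fy / 3.0; F(i1, 2) += fz / 3.0;
      A[i1] += Aclip / 3.0;
    }
    tot[0] += fx; tot[1] += fy; tot[2] += fz;
    diag.push_back(t + 1); diag.push_back(a); diag.push_back(c);
    diag.push_back(lambda); diag.push_back(Fn); diag.push_back(Aclip);
    diag.push_back(delta); diag.push_back(gmin);
  }
  int npatch = diag.size() / 8;
  NumericMatrix patches(npatch, 8);
  for (int i = 0; i < npatch; ++i)
    for (int j = 0; j < 8; ++j) patches(i, j) = diag[8 * i + j];
  colnames(patches) = CharacterVector::create("t", "a", "c", "lambda", "Fn",
                                              "area", "delta", "gmin");
  return List::create(_["F"] = F, _["area"] = A,
                      _["total"] = NumericVector::create(tot[0], tot[1], tot[2]),
                      _["body_force"] = NumericVector::create(-tot[0], -tot[1], -tot[2]),
                      _["patches"] = patches);
}
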