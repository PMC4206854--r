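// Compiled stepping engine: bending/gliding/contact/wall forces, LINCS
// constraint projection, neighbour lists and the adaptive Euler loop.
// All quantities SI (m, s, N). Mirrors the exported R reference functions;
// parity is enforced by tests.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Par {
  double theta, l, alpha, zeta, v0, omega, epsilon, eps_rep;
  double b_aniso, cap_R, wall_c, W, H, D;
  double abs_accuracy, dt_max, dt_min, lincs_tol;
  int lincs_maxit;
};

Par read_par(const List& par) {
  Par p;
  p.theta = par["theta"]; p.l = par["l"]; p.alpha = par["alpha"];
  p.zeta = par["zeta"]; p.v0 = par["v0"]; p.omega = par["omega"];
  p.epsilon = par["epsilon"]; p.eps_rep = par["eps_rep"];
  p.b_aniso = par["b_aniso"]; p.cap_R = par["cap_R"]; p.wall_c = par["wall_c"];
  p.W = par["W"]; p.H = par["H"]; p.D = par["D"];
  p.abs_accuracy = par["abs_accuracy"];
  p.dt_max = par["dt_max"]; p.dt_min = par["dt_min"];
  p.lincs_tol = par["lincs_tol"];
  p.lincs_maxit = par["lincs_maxit"];
  return p;
}

struct Topology {
  int nV = 0, nE = 0, nT = 0;
  std::vector<int> voff;        // vertex offset per trichome, length nT+1
  std::vector<int> e_first;     // global first-vertex index per edge
  std::vector<int> e_tri;       // trichome id per edge
  std::vector<int> e_local;     // edge index within its trichome
  std::vector<uint8_t> v_tip;   // vertex is a trichome tip
};

Topology make_topology(const IntegerVector& offsets) {
  Topology tp;
  tp.nT = offsets.size() - 1;
  tp.voff.assign(offsets.begin(), offsets.end());
  tp.nV = tp.voff[tp.nT];
  tp.v_tip.assign(tp.nV, 0);
  for (int f = 0; f < tp.nT; ++f) {
    int a = tp.voff[f], b = tp.voff[f + 1];
    if (b - a < 2) stop("each trichome needs at least 2 vertices");
    tp.v_tip[a] = 1; tp.v_tip[b - 1] = 1;
    for (int i = a; i < b - 1; ++i) {
      tp.e_first.push_back(i);
      tp.e_tri.push_back(f);
      tp.e_local.push_back(i - a);
    }
  }
  tp.nE = (int)tp.e_first.size();
  return tp;
}

typedef std::vector<double> vec;

inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
inline void cross3(const double* a, const double* b, double* o) {
  o[0] = a[1] * b[2] - a[2] * b[1];
  o[1] = a[2] * b[0] - a[0] * b[2];
  o[2] = a[0] * b[1] - a[1] * b[0];
}

// Head-ward unit tangents for every vertex (x: nV x 3 row-major).
void vertex_tangents(const vec& x, const Topology& tp, vec& tg) {
  tg.assign(3 * tp.nV, 0.0);
  for (int f = 0; f < tp.nT; ++f) {
    int a = tp.voff[f], b = tp.voff[f + 1];
    for (int i = a; i < b; ++i) {
      int lo = (i == a) ? i : i - 1;
      int hi = (i == b - 1) ? i : i + 1;
      double t[3] = { x[3 * hi] - x[3 * lo], x[3 * hi + 1] - x[3 * lo + 1],
                      x[3 * hi + 2] - x[3 * lo + 2] };
      double n = std::sqrt(dot3(t, t));
      if (n <= 0) stop("degenerate tangent (coincident vertices)");
      tg[3 * i] = t[0] / n; tg[3 * i + 1] = t[1] / n; tg[3 * i + 2] = t[2] / n;
    }
  }
}

// Bending force: exact negative gradient of E = (alpha/l) * sum ||kb_j||^2.
void add_bending_forces(const vec& x, const Topology& tp, const Par& p, vec& F) {
  double pref = p.alpha / p.l;
  for (int f = 0; f < tp.nT; ++f) {
    int a = tp.voff[f], b = tp.voff[f + 1];
    for (int j = a + 1; j < b - 1; ++j) {
      const double* xm = &x[3 * (j - 1)];
      const double* x0 = &x[3 * j];
      const double* xp = &x[3 * (j + 1)];
      double e0[3] = { x0[0] - xm[0], x0[1] - xm[1], x0[2] - xm[2] };
      double e1[3] = { xp[0] - x0[0], xp[1] - x0[1], xp[2] - x0[2] };
      double n0 = std::sqrt(dot3(e0, e0)), n1 = std::sqrt(dot3(e1, e1));
      double denom = n0 * n1 + dot3(e0, e1);
      if (denom <= 1e-12 * n0 * n1) stop("anti-parallel adjacent edges");
      double kb[3]; cross3(e0, e1, kb);
      for (int d = 0; d < 3; ++d) kb[d] *= 2.0 / denom;
      double kb2 = dot3(kb, kb);
      double c0[3], c1[3];
      cross3(e1, kb, c0);  // for grad wrt e0
      cross3(kb, e0, c1);  // for grad wrt e1
      double g0[3], g1[3];
      for (int d = 0; d < 3; ++d) {
        g0[d] = (4.0 / denom) * c0[d] -
                (2.0 * kb2 / denom) * ((n1 / n0) * e0[d] + e1[d]);
        g1[d] = (4.0 / denom) * c1[d] -
                (2.0 * kb2 / denom) * ((n0 / n1) * e1[d] + e0[d]);
      }
      double* Fm = &F[3 * (j - 1)];
      double* F0 = &F[3 * j];
      double* Fp = &F[3 * (j + 1)];
      for (int d = 0; d < 3; ++d) {
        Fm[d] += pref * g0[d];
        F0[d] += pref * (g1[d] - g0[d]);
        Fp[d] += -pref * g1[d];
      }
    }
  }
}

void add_gliding_forces(const vec& tg, const Topology& tp,
                        const IntegerVector& polarity, const Par& p, vec& F) {
  if (p.v0 <= 0) return;
  for (int f = 0; f < tp.nT; ++f) {
    double mag = p.zeta * p.v0 * (double)polarity[f];
    for (int i = tp.voff[f]; i < tp.voff[f + 1]; ++i)
      for (int d = 0; d < 3; ++d) F[3 * i + d] += mag * tg[3 * i + d];
  }
}

void add_wall_forces(const vec& x, const Topology& tp, const Par& p, vec& F) {
  double zhi = p.H - p.theta / 2.0, zlo = p.theta / 2.0;
  for (int i = 0; i < tp.nV; ++i) {
    double z = x[3 * i + 2];
    if (z > zhi) F[3 * i + 2] += p.wall_c * (zhi - z);
    else if (z < zlo) F[3 * i + 2] += p.wall_c * (zlo - z);
  }
}

// ---- contact ---------------------------------------------------------------

struct Interaction { double a, b, h[3], dist; };

// Admissible interactions between edges (x1,x2) and (x3,x4) with head-ward
// vertex tangents t1..t4 and tip flags. Returns count (max 4) in out[].
int admissible(const double* x1, const double* x2, const double* x3,
               const double* x4, const double* t1, const double* t2,
               const double* t3, const double* t4,
               bool tip1, bool tip2, bool tip3, bool tip4,
               Interaction* out) {
  double d1[3] = { x2[0] - x1[0], x2[1] - x1[1], x2[2] - x1[2] };
  double d2[3] = { x4[0] - x3[0], x4[1] - x3[1], x4[2] - x3[2] };
  double r[3]  = { x3[0] - x1[0], x3[1] - x1[1], x3[2] - x1[2] };
  double d11 = dot3(d1, d1), d22 = dot3(d2, d2), d12 = dot3(d1, d2);
  double det = d11 * d22 - d12 * d12;
  auto hvec = [&](double a, double b, double* h) {
    for (int d = 0; d < 3; ++d)
      h[d] = (b * x4[d] + (1 - b) * x3[d]) - (a * x2[d] + (1 - a) * x1[d]);
  };
  if (det > 1e-12 * d11 * d22) {
    double ax = (d22 * dot3(d1, r) - d12 * dot3(d2, r)) / det;
    double bx = (d12 * dot3(d1, r) - d11 * dot3(d2, r)) / det;
    if (ax > 0 && ax < 1 && bx > 0 && bx < 1) {
      out[0].a = ax; out[0].b = bx;
      hvec(ax, bx, out[0].h);
      out[0].dist = std::sqrt(dot3(out[0].h, out[0].h));
      return 1;
    }
  }
  int n = 0;
  auto push = [&](double a, double b) {
    for (int k = 0; k < n; ++k)
      if (std::fabs(out[k].a - a) < 1e-12 && std::fabs(out[k].b - b) < 1e-12)
        return;
    out[n].a = a; out[n].b = b;
    hvec(a, b, out[n].h);
    out[n].dist = std::sqrt(dot3(out[n].h, out[n].h));
    ++n;
  };
  auto clampp = [](double v) { return v < 0 ? 0.0 : (v > 1 ? 1.0 : v); };
  auto slab = [&](const double* xk, const double* xi, const double* xj,
                  const double* ti, const double* tj, bool ei, bool ej) {
    double ri[3] = { xk[0] - xi[0], xk[1] - xi[1], xk[2] - xi[2] };
    double rj[3] = { xk[0] - xj[0], xk[1] - xj[1], xk[2] - xj[2] };
    return (dot3(ri, ti) >= 0 || ei) && (dot3(rj, tj) < 0 || ej);
  };
  double h[3];
  // h1: vertex x3 vs edge <x1,x2>
  if (slab(x3, x1, x2, t1, t2, tip1, tip2)) {
    double a = clampp(dot3(r, d1) / d11);
    hvec(a, 0, h);
    if (dot3(h, t3) <= 0 || tip3) push(a, 0);
  }
  // h2: vertex x4 vs edge <x1,x2>
  if (slab(x4, x1, x2, t1, t2, tip1, tip2)) {
    double r14[3] = { x4[0] - x1[0], x4[1] - x1[1], x4[2] - x1[2] };
    double a = clampp(dot3(r14, d1) / d11);
    hvec(a, 1, h);
    if (dot3(h, t4) > 0 || tip4) push(a, 1);
  }
  // h3: vertex x1 vs edge <x3,x4>
  if (slab(x1, x3, x4, t3, t4, tip3, tip4)) {
    double r31[3] = { x1[0] - x3[0], x1[1] - x3[1], x1[2] - x3[2] };
    double b = clampp(dot3(r31, d2) / d22);
    hvec(0, b, h);
    if (dot3(h, t1) <= 0 || tip1) push(0, b);
  }
  // h4: vertex x2 vs edge <x3,x4>
  if (slab(x2, x3, x4, t3, t4, tip3, tip4)) {
    double r32[3] = { x2[0] - x3[0], x2[1] - x3[1], x2[2] - x3[2] };
    double b = clampp(dot3(r32, d2) / d22);
    hvec(1, b, h);
    if (dot3(h, t2) > 0 || tip2) push(1, b);
  }
  // a capsule pair has at most two true contact regions: keep the two
  // nearest candidates
  while (n > 2) {
    int worst = 0;
    for (int k = 1; k < n; ++k)
      if (out[k].dist > out[worst].dist) worst = k;
    out[worst] = out[n - 1];
    --n;
  }
  return n;
}

// Closest distance between two segments (Ericson-style), used for the
// relaxation stopping rule and diagnostics.
double segment_distance(const double* p1, const double* q1,
                        const double* p2, const double* q2) {
  double d1[3] = { q1[0] - p1[0], q1[1] - p1[1], q1[2] - p1[2] };
  double d2[3] = { q2[0] - p2[0], q2[1] - p2[1], q2[2] - p2[2] };
  double rr[3] = { p1[0] - p2[0], p1[1] - p2[1], p1[2] - p2[2] };
  double a = dot3(d1, d1), e = dot3(d2, d2), f = dot3(d2, rr);
  double s = 0, t = 0;
  const double EPS = 1e-30;
  if (a <= EPS && e <= EPS) { s = t = 0; }
  else if (a <= EPS) { t = std::min(1.0, std::max(0.0, f / e)); }
  else {
    double c = dot3(d1, rr);
    if (e <= EPS) { s = std::min(1.0, std::max(0.0, -c / a)); }
    else {
      double b = dot3(d1, d2);
      double denom = a * e - b * b;
      if (denom > 0) s = std::min(1.0, std::max(0.0, (b * f - c * e) / denom));
      else s = 0;
      t = (b * s + f) / e;
      if (t < 0) { t = 0; s = std::min(1.0, std::max(0.0, -c / a)); }
      else if (t > 1) { t = 1; s = std::min(1.0, std::max(0.0, (b - c) / a)); }
    }
  }
  double c1[3], c2[3];
  for (int d = 0; d < 3; ++d) {
    c1[d] = p1[d] + d1[d] * s;
    c2[d] = p2[d] + d2[d] * t;
  }
  double dd[3] = { c1[0] - c2[0], c1[1] - c2[1], c1[2] - c2[2] };
  return std::sqrt(dot3(dd, dd));
}

struct NeighborList {
  std::vector<std::pair<int, int> > pairs;  // global edge id pairs, i < j
  vec x_build;                              // positions at build time
};

inline double wrap_coord(double v, double box) {
  double w = v - box * std::floor(v / box);
  if (w >= box) w -= box;  // guard against rounding at the boundary
  return w;
}

void edge_midpoint(const vec& x, const Topology& tp, int e, double* m) {
  int i = tp.e_first[e];
  for (int d = 0; d < 3; ++d) m[d] = 0.5 * (x[3 * i + d] + x[3 * (i + 1) + d]);
}

inline bool excluded_pair(const Topology& tp, int e1, int e2) {
  return tp.e_tri[e1] == tp.e_tri[e2] &&
         std::abs(tp.e_local[e1] - tp.e_local[e2]) <= 2;
}

// Broad phase: uniform cells in x,y (min-image), midpoint cutoff 2*theta + l
// (a superset of all pairs with true separation < 2*theta).
void build_neighbor_list(const vec& x, const Topology& tp, const Par& p,
                         NeighborList& nl) {
  nl.pairs.clear();
  nl.x_build = x;
  double cutoff = 2 * p.theta + p.l;
  double cut2 = cutoff * cutoff;
  int nx = std::max(1, (int)std::floor(p.W / cutoff));
  int ny = std::max(1, (int)std::floor(p.D / cutoff));
  std::vector<double> mid(3 * tp.nE);
  for (int e = 0; e < tp.nE; ++e) edge_midpoint(x, tp, e, &mid[3 * e]);

  auto consider = [&](int e1, int e2) {
    if (e2 <= e1 || excluded_pair(tp, e1, e2)) return;
    double dx = mid[3 * e1] - mid[3 * e2];
    double dy = mid[3 * e1 + 1] - mid[3 * e2 + 1];
    double dz = mid[3 * e1 + 2] - mid[3 * e2 + 2];
    dx -= p.W * std::round(dx / p.W);
    dy -= p.D * std::round(dy / p.D);
    if (dx * dx + dy * dy + dz * dz < cut2)
      nl.pairs.push_back(std::make_pair(e1, e2));
  };

  if (nx < 3 || ny < 3) {  // domain too small for cells: all pairs
    for (int e1 = 0; e1 < tp.nE; ++e1)
      for (int e2 = e1 + 1; e2 < tp.nE; ++e2) consider(e1, e2);
    return;
  }
  double cw = p.W / nx, cd = p.D / ny;
  std::vector<std::vector<int> > cells(nx * ny);
  std::vector<int> cellof(tp.nE);
  for (int e = 0; e < tp.nE; ++e) {
    int cx = (int)(wrap_coord(mid[3 * e], p.W) / cw); if (cx >= nx) cx = nx - 1;
    int cy = (int)(wrap_coord(mid[3 * e + 1], p.D) / cd); if (cy >= ny) cy = ny - 1;
    int c = cy * nx + cx;
    cells[c].push_back(e);
    cellof[e] = c;
  }
  for (int cy = 0; cy < ny; ++cy) {
    for (int cx = 0; cx < nx; ++cx) {
      const std::vector<int>& A = cells[cy * nx + cx];
      if (A.empty()) continue;
      for (int oy = -1; oy <= 1; ++oy) {
        for (int ox = -1; ox <= 1; ++ox) {
          int cx2 = (cx + ox + nx) % nx, cy2 = (cy + oy + ny) % ny;
          const std::vector<int>& B = cells[cy2 * nx + cx2];
          for (size_t ia = 0; ia < A.size(); ++ia)
            for (size_t ib = 0; ib < B.size(); ++ib)
              consider(A[ia], B[ib]);
        }
      }
    }
  }
}

bool list_stale(const vec& x, const NeighborList& nl, const Par& p) {
  double th2 = p.theta * p.theta;
  for (size_t i = 0; i < x.size(); i += 3) {
    double dx = x[i] - nl.x_build[i];
    double dy = x[i + 1] - nl.x_build[i + 1];
    double dz = x[i + 2] - nl.x_build[i + 2];
    if (dx * dx + dy * dy + dz * dz >= th2) return true;
  }
  return false;
}

// LJ signed magnitude; positive = repulsive. Truncated at 2*theta; repulsive
// branch capped at cap_R. repulsion_only suppresses attraction and uses
// eps_rep for the hard core.
inline double lj_mag(double h, const Par& p, bool repulsion_only) {
  if (h >= 2 * p.theta) return 0.0;
  double eps = repulsion_only ? p.eps_rep : p.epsilon;
  double s = p.theta / h;
  double s2 = s * s, s4 = s2 * s2, s6 = s4 * s2, s7 = s6 * s, s13 = s6 * s7;
  double f = 0.5 * eps * (s13 - s7);
  if (repulsion_only && f < 0) return 0.0;
  if (f > p.cap_R) f = p.cap_R;
  return f;
}

void add_contact_forces(const vec& x, const vec& tg, const Topology& tp,
                        const Par& p, const NeighborList& nl,
                        bool repulsion_only, vec& F) {
  if (p.epsilon <= 0 && !repulsion_only && p.eps_rep <= 0) return;
  bool rep = repulsion_only || p.epsilon <= 0;  // cohesionless hard core
  Interaction ints[4];
  for (size_t k = 0; k < nl.pairs.size(); ++k) {
    int e1 = nl.pairs[k].first, e2 = nl.pairs[k].second;
    int i1 = tp.e_first[e1], i2 = i1 + 1;
    int i3 = tp.e_first[e2], i4 = i3 + 1;
    const double* x1 = &x[3 * i1];
    const double* x2 = &x[3 * i2];
    double mx = 0.5 * (x1[0] + x2[0]) - 0.5 * (x[3 * i3] + x[3 * i4]);
    double my = 0.5 * (x1[1] + x2[1]) - 0.5 * (x[3 * i3 + 1] + x[3 * i4 + 1]);
    double sx = p.W * std::round(mx / p.W);
    double sy = p.D * std::round(my / p.D);
    double x3[3] = { x[3 * i3] + sx, x[3 * i3 + 1] + sy, x[3 * i3 + 2] };
    double x4[3] = { x[3 * i4] + sx, x[3 * i4 + 1] + sy, x[3 * i4 + 2] };
    int n = admissible(x1, x2, x3, x4, &tg[3 * i1], &tg[3 * i2], &tg[3 * i3],
                       &tg[3 * i4], tp.v_tip[i1], tp.v_tip[i2],
                       tp.v_tip[i3], tp.v_tip[i4], ints);
    for (int q = 0; q < n; ++q) {
      double h = ints[q].dist;
      if (h <= 0) stop("overlapping centerlines in contact force");
      double f = lj_mag(h, p, rep);
      if (f == 0) continue;
      double a = ints[q].a, b = ints[q].b;
      // force on edge 1 is -f * hhat (repulsion pushes the edges apart)
      for (int d = 0; d < 3; ++d) {
        double Fc = -f * ints[q].h[d] / h;
        F[3 * i1 + d] += (1 - a) * Fc;
        F[3 * i2 + d] += a * Fc;
        F[3 * i3 + d] -= (1 - b) * Fc;
        F[3 * i4 + d] -= b * Fc;
      }
    }
  }
}

void total_forces(const vec& x, const Topology& tp, const Par& p,
                  const IntegerVector& polarity, const NeighborList& nl,
                  bool repulsion_only, vec& tg, vec& F) {
  F.assign(3 * tp.nV, 0.0);
  vertex_tangents(x, tp, tg);
  add_bending_forces(x, tp, p, F);
  add_gliding_forces(tg, tp, polarity, p, F);
  add_wall_forces(x, tp, p, F);
  add_contact_forces(x, tg, tp, p, nl, repulsion_only, F);
}

// Anisotropic mobility: v = (1/zeta) [ (F.t)t + (F - (F.t)t)/b ].
void project_velocities(const vec& F, const vec& tg, const Par& p, vec& v) {
  int n = (int)F.size() / 3;
  v.resize(F.size());
  for (int i = 0; i < n; ++i) {
    const double* Fi = &F[3 * i];
    const double* ti = &tg[3 * i];
    double ft = dot3(Fi, ti);
    for (int d = 0; d < 3; ++d) {
      double fpar = ft * ti[d];
      v[3 * i + d] = (fpar + (Fi[d] - fpar) / p.b_aniso) / p.zeta;
    }
  }
}

// LINCS-style constraint projection for one chain: corrections act along
// the reference bond directions; the constraint coupling matrix S = B B^T
// (tridiagonal for a chain: diagonal 2, off-diagonal -u_k.u_{k+1}) is
// solved exactly with the Thomas algorithm and the correction is iterated
// until all bond lengths are within lincs_tol * l. (A truncated series
// expansion of S^{-1} is impractically slow for long straight chains,
// where the coupling spectral radius approaches 1.) Returns false on
// non-convergence.
bool lincs_chain(vec& x, const vec& xref, int a, int b, const Par& p) {
  int nb = b - a - 1;
  if (nb < 1) return true;
  std::vector<double> u(3 * nb), g(nb), lam(nb), cw(nb);
  for (int k = 0; k < nb; ++k) {
    double e[3] = { xref[3 * (a + k + 1)] - xref[3 * (a + k)],
                    xref[3 * (a + k + 1) + 1] - xref[3 * (a + k) + 1],
                    xref[3 * (a + k + 1) + 2] - xref[3 * (a + k) + 2] };
    double n = std::sqrt(dot3(e, e));
    if (n <= 0) return false;
    for (int d = 0; d < 3; ++d) u[3 * k + d] = e[d] / n;
  }
  // off-diagonal couplings of S = B B^T (diag = 2): -u_k . u_{k+1}
  std::vector<double> cpl(nb > 1 ? nb - 1 : 0);
  for (int k = 0; k + 1 < nb; ++k)
    cpl[k] = dot3(&u[3 * k], &u[3 * (k + 1)]);
  double tol = p.lincs_tol * p.l;
  for (int it = 0; it < p.lincs_maxit; ++it) {
    double maxerr = 0;
    for (int k = 0; k < nb; ++k) {
      double e[3] = { x[3 * (a + k + 1)] - x[3 * (a + k)],
                      x[3 * (a + k + 1) + 1] - x[3 * (a + k) + 1],
                      x[3 * (a + k + 1) + 2] - x[3 * (a + k) + 2] };
      double len = std::sqrt(dot3(e, e));
      g[k] = len - p.l;
      double err = std::fabs(g[k]);
      if (err > maxerr) maxerr = err;
    }
    if (maxerr < tol) return true;
    // solve S lam = g, S tridiagonal with diag 2, off-diag -cpl (Thomas)
    {
      double beta = 2.0;
      lam[0] = g[0] / beta;
      for (int k = 1; k < nb; ++k) {
        cw[k] = -cpl[k - 1] / beta;
        beta = 2.0 + cpl[k - 1] * cw[k];
        lam[k] = (g[k] + cpl[k - 1] * lam[k - 1]) / beta;
      }
      for (int k = nb - 2; k >= 0; --k) lam[k] -= cw[k + 1] * lam[k + 1];
    }
    // x <- x - B^T lam : vertex j moves by lam_j u_j - lam_{j-1} u_{j-1}
    for (int j = 0; j <= nb; ++j) {
      for (int d = 0; d < 3; ++d) {
        double dx = 0;
        if (j < nb) dx += lam[j] * u[3 * j + d];
        if (j > 0) dx -= lam[j - 1] * u[3 * (j - 1) + d];
        x[3 * (a + j) + d] += dx;
      }
    }
  }
  return false;
}

bool lincs_all(vec& x, const vec& xref, const Topology& tp, const Par& p) {
  for (int f = 0; f < tp.nT; ++f)
    if (!lincs_chain(x, xref, tp.voff[f], tp.voff[f + 1], p)) return false;
  return true;
}

vec as_vec(const NumericMatrix& m) {
  int n = m.nrow();
  vec x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = m(i, d);
  return x;
}

NumericMatrix as_mat(const vec& x) {
  int n = (int)x.size() / 3;
  NumericMatrix m(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) m(i, d) = x[3 * i + d];
  return m;
}

} // namespace

// [[Rcpp::export]]
NumericMatrix cpp_total_forces(NumericMatrix pos, IntegerVector offsets,
                               IntegerVector polarity, List par,
                               bool repulsion_only = false) {
  Topology tp = make_topology(offsets);
  Par p = read_par(par);
  vec x = as_vec(pos);
  NeighborList nl;
  build_neighbor_list(x, tp, p, nl);
  vec tg, F;
  total_forces(x, tp, p, polarity, nl, repulsion_only, tg, F);
  return as_mat(F);
}

// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_pairs(NumericMatrix pos, IntegerVector offsets,
                                 List par) {
  Topology tp = make_topology(offsets);
  Par p = read_par(par);
  vec x = as_vec(pos);
  NeighborList nl;
  build_neighbor_list(x, tp, p, nl);
  IntegerMatrix out((int)nl.pairs.size(), 2);
  for (size_t k = 0; k < nl.pairs.size(); ++k) {
    out(k, 0) = nl.pairs[k].first + 1;   // 1-based edge ids for R
    out(k, 1) = nl.pairs[k].second + 1;
  }
  return out;
}

// Direct access to the engine's admissibility logic for parity tests with
// the R reference implementation.
// [[Rcpp::export]]
NumericMatrix cpp_admissible(NumericVector x1, NumericVector x2,
                             NumericVector x3, NumericVector x4,
                             NumericVector t1, NumericVector t2,
                             NumericVector t3, NumericVector t4,
                             LogicalVector tips) {
  Interaction ints[4];
  int n = admissible(REAL(x1), REAL(x2), REAL(x3), REAL(x4), REAL(t1),
                     REAL(t2), REAL(t3), REAL(t4), tips[0], tips[1],
                     tips[2], tips[3], ints);
  NumericMatrix out(n, 3);
  for (int k = 0; k < n; ++k) {
    out(k, 0) = ints[k].a; out(k, 1) = ints[k].b; out(k, 2) = ints[k].dist;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_lincs(NumericMatrix proposed, NumericMatrix reference,
               IntegerVector offsets, List par) {
  Topology tp = make_topology(offsets);
  Par p = read_par(par);
  vec x = as_vec(proposed), xr = as_vec(reference);
  bool ok = lincs_all(x, xr, tp, p);
  return List::create(_["pos"] = as_mat(x), _["converged"] = ok);
}

// [[Rcpp::export]]
double cpp_min_separation(NumericMatrix pos, IntegerVector offsets, List par) {
  Topology tp = make_topology(offsets);
  Par p = read_par(par);
  vec x = as_vec(pos);
  NeighborList nl;
  build_neighbor_list(x, tp, p, nl);
  double best = R_PosInf;
  for (size_t k = 0; k < nl.pairs.size(); ++k) {
    int e1 = nl.pairs[k].first, e2 = nl.pairs[k].second;
    int i1 = tp.e_first[e1], i3 = tp.e_first[e2];
    const double* x1 = &x[3 * i1];
    const double* x2 = &x[3 * (i1 + 1)];
    double mx = 0.5 * (x1[0] + x2[0]) - 0.5 * (x[3 * i3] + x[3 * (i3 + 1)]);
    double my = 0.5 * (x1[1] + x2[1]) - 0.5 * (x[3 * i3 + 1] + x[3 * (i3 + 1) + 1]);
    double sx = p.W * std::round(mx / p.W);
    double sy = p.D * std::round(my / p.D);
    double x3[3] = { x[3 * i3] + sx, x[3 * i3 + 1] + sy, x[3 * i3 + 2] };
    double x4[3] = { x[3 * (i3 + 1)] + sx, x[3 * (i3 + 1) + 1] + sy,
                     x[3 * (i3 + 1) + 2] };
    double d = segment_distance(x1, x2, x3, x4);
    if (d < best) best = d;
  }
  return best;
}

// Adaptive Euler with step-doubling error control, LINCS after every
// unconstrained substep, reversal sampling on accepted steps and
// neighbour-list reuse until a vertex has moved theta.
// [[Rcpp::export]]
List cpp_advance(NumericMatrix pos, IntegerVector offsets,
                 IntegerVector polarity, List par, double t, double t_target,
                 double dt, bool repulsion_only = false,
                 bool reversals = true, int max_steps = -1) {
  Topology tp = make_topology(offsets);
  Par p = read_par(par);
  vec x = as_vec(pos);
  IntegerVector P = clone(polarity);

  NeighborList nl;
  build_neighbor_list(x, tp, p, nl);
  long n_rebuild = 0, n_accept = 0, n_reject = 0;
  double max_err_seen = 0;

  vec tg, F, v, x1, xa, x2, Fa, va, tga;
  if (dt <= 0) dt = p.dt_min * 10;

  bool haveF = false;
  while (t < t_target) {
    if (max_steps >= 0 && n_accept >= max_steps) break;
    if (dt > p.dt_max) dt = p.dt_max;
    double dt_use = std::min(dt, t_target - t);

    if (!haveF) {
      total_forces(x, tp, p, P, nl, repulsion_only, tg, F);
      project_velocities(F, tg, p, v);
      haveF = true;
    }
    // full step
    x1 = x;
    for (size_t i = 0; i < x.size(); ++i) x1[i] += v[i] * dt_use;
    bool ok1 = lincs_all(x1, x, tp, p);
    // two half steps
    xa = x;
    for (size_t i = 0; i < x.size(); ++i) xa[i] += v[i] * (dt_use / 2);
    bool ok2 = lincs_all(xa, x, tp, p);
    bool ok3 = false;
    double err = R_PosInf;
    if (ok1 && ok2) {
      total_forces(xa, tp, p, P, nl, repulsion_only, tga, Fa);
      project_velocities(Fa, tga, p, va);
      x2 = xa;
      for (size_t i = 0; i < x.size(); ++i) x2[i] += va[i] * (dt_use / 2);
      ok3 = lincs_all(x2, xa, tp, p);
      if (ok3) {
        double m2 = 0;
        for (size_t i = 0; i < x.size(); i += 3) {
          double dx = x1[i] - x2[i], dy = x1[i + 1] - x2[i + 1],
                 dz = x1[i + 2] - x2[i + 2];
          double s = dx * dx + dy * dy + dz * dz;
          if (s > m2) m2 = s;
        }
        err = std::sqrt(m2);
      }
    }

    if (ok1 && ok2 && ok3 && err <= p.abs_accuracy) {
      // accept the two-half-step solution
      x.swap(x2);
      t += dt_use;
      ++n_accept;
      if (err > max_err_seen) max_err_seen = err;
      haveF = false;
      if (reversals && p.omega > 0) {
        double pr = p.omega * dt_use;
        for (int f = 0; f < tp.nT; ++f)
          if (unif_rand() < pr) P[f] = -P[f];
      }
      if (list_stale(x, nl, p)) {
        build_neighbor_list(x, tp, p, nl);
        ++n_rebuild;
      }
      double fac = (err > 0) ? 0.9 * std::sqrt(p.abs_accuracy / err) : 1.5;
      if (fac > 1.5) fac = 1.5;
      if (fac < 0.2) fac = 0.2;
      dt = dt_use * fac;
    } else {
      ++n_reject;
      double fac = 0.5;
      if (ok1 && ok2 && ok3 && R_finite(err) && err > 0)
        fac = 0.9 * std::sqrt(p.abs_accuracy / err);
      if (fac > 0.5) fac = 0.5;
      if (fac < 0.1) fac = 0.1;
      dt = dt_use * fac;
      if (dt < p.dt_min)
        stop("adaptive step size underflow (dt < dt_min): system too stiff at requested accuracy");
    }
  }

  return List::create(_["pos"] = as_mat(x), _["polarity"] = P, _["t"] = t,
                      _["dt"] = dt, _["n_accept"] = (double)n_accept,
                      _["n_reject"] = (double)n_reject,
                      _["n_rebuild"] = (double)n_rebuild,
                      _["max_err"] = max_err_seen);
}
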