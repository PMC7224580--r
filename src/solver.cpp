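// Exhaustive solver for the bivariate steady-state system {Phi1 = 0, Phi2 = 0}.
//
// Hidden-variable elimination: the Sylvester resultant in v (entries are
// degree-<=4 polynomials in u) is obtained by evaluating its determinant at
// scaled roots of unity and interpolating by inverse DFT.  Univariate roots
// come from Aberth-Ehrlich iteration, v is recovered by back-substitution,
// and every candidate pair is polished by Newton's method on the full
// system.  The multiplicity of the u = 0 root of the resultant gives the
// local intersection multiplicity of the origin once no other solution has
// u near 0.
//
// Coefficient grids are length-25 arrays, column-major: c[i + 5*j]
// multiplies u^i v^j.

#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;
typedef std::complex<double> cplx;

static const double TRIM_REL = 1e-11;   // trailing-coefficient trim
static const double CAND_REL = 1e-5;    // loose pre-Newton residual filter
static const double ACCEPT_REL = 1e-9;  // final relative residual bound
static const double DEDUP_REL = 1e-8;
static const double DRIFT_REL = 0.25;   // max Newton drift, relative to root

struct SolveOpts {
  double t_zmin, t_zmax, t_inf, newton_tol;
  int expected_nf;          // 7 weak, 5 strong, <=0 to skip generic checks
  int max_retry;            // retry ladder cap (spec: 2)
};

enum CoordClass { CL_SMALL = 0, CL_AMBIG, CL_INF, CL_NZREAL, CL_NZNONREAL };

// Eq-31 case analysis, evaluated in the printed order.
static int classify_coord(cplx x, double t_zmin, double t_zmax, double t_inf) {
  double a = std::fabs(x.real()), b = std::fabs(x.imag());
  if (a < t_zmax && b < t_zmax) return CL_SMALL;
  if (b > t_zmin && b < t_zmax) return CL_AMBIG;
  if (a > t_inf || b > t_inf) return CL_INF;
  if (a > t_zmax && a < t_inf && b < t_zmin) return CL_NZREAL;
  return CL_NZNONREAL;
}

// evaluate Phi(u, v) together with the sum of absolute monomial terms
static cplx eval_grid(const double* g, cplx u, cplx v, double* scale) {
  cplx pu[5], pv[5];
  pu[0] = 1.0; pv[0] = 1.0;
  for (int i = 1; i < 5; ++i) { pu[i] = pu[i - 1] * u; pv[i] = pv[i - 1] * v; }
  cplx acc(0.0, 0.0);
  double s = 0.0;
  for (int j = 0; j < 5; ++j)
    for (int i = 0; i < 5; ++i) {
      double c = g[i + 5 * j];
      if (c != 0.0) {
        cplx term = c * pu[i] * pv[j];
        acc += term;
        s += std::abs(term);
      }
    }
  if (scale) *scale = (s > 1.0) ? s : 1.0;
  return acc;
}

static void eval_grid_jac(const double* g, cplx u, cplx v,
                          cplx* f, cplx* fu, cplx* fv) {
  cplx pu[5], pv[5];
  pu[0] = 1.0; pv[0] = 1.0;
  for (int i = 1; i < 5; ++i) { pu[i] = pu[i - 1] * u; pv[i] = pv[i - 1] * v; }
  *f = *fu = *fv = cplx(0.0, 0.0);
  for (int j = 0; j < 5; ++j)
    for (int i = 0; i < 5; ++i) {
      double c = g[i + 5 * j];
      if (c == 0.0) continue;
      *f += c * pu[i] * pv[j];
      if (i > 0) *fu += c * double(i) * pu[i - 1] * pv[j];
      if (j > 0) *fv += c * double(j) * pu[i] * pv[j - 1];
    }
}

// LU determinant with partial pivoting, m <= 8
static cplx det_lu(cplx* M, int m) {
  cplx det(1.0, 0.0);
  for (int k = 0; k < m; ++k) {
    int piv = k;
    double best = std::abs(M[k * m + k]);
    for (int i = k + 1; i < m; ++i) {
      double a = std::abs(M[i * m + k]);
      if (a > best) { best = a; piv = i; }
    }
    if (best == 0.0) return cplx(0.0, 0.0);
    if (piv != k) {
      for (int j = 0; j < m; ++j) std::swap(M[k * m + j], M[piv * m + j]);
      det = -det;
    }
    det *= M[k * m + k];
    cplx inv = 1.0 / M[k * m + k];
    for (int i = k + 1; i < m; ++i) {
      cplx f = M[i * m + k] * inv;
      if (f == cplx(0.0, 0.0)) continue;
      for (int j = k + 1; j < m; ++j) M[i * m + j] -= f * M[k * m + j];
    }
  }
  return det;
}

// Aberth-Ehrlich on ascending complex coefficients (a.back() != 0).
// Initial radii come from the Newton polygon (upper convex hull of
// (j, log|a_j|)), which handles root magnitudes spread over many decades.
static bool aberth(const std::vector<cplx>& a, std::vector<cplx>& roots) {
  int d = (int)a.size() - 1;
  roots.assign(d, cplx(0.0, 0.0));
  if (d < 1) return true;
  if (d == 1) { roots[0] = -a[0] / a[1]; return true; }
  std::vector<int> hx;           // hull vertex indices
  {
    std::vector<double> ly(d + 1);
    for (int j = 0; j <= d; ++j)
      ly[j] = (std::abs(a[j]) > 0.0) ? std::log(std::abs(a[j])) : -1e300;
    for (int j = 0; j <= d; ++j) {
      if (ly[j] <= -1e299 && j != 0 && j != d) continue;
      while (hx.size() >= 2) {
        int p = hx[hx.size() - 2], q = hx[hx.size() - 1];
        // keep the hull upper-convex
        if ((ly[q] - ly[p]) * (j - q) <= (ly[j] - ly[q]) * (q - p))
          hx.pop_back();
        else break;
      }
      hx.push_back(j);
    }
  }
  int placed = 0;
  for (size_t s = 0; s + 1 < hx.size(); ++s) {
    int j1 = hx[s], j2 = hx[s + 1];
    double r = std::pow(std::abs(a[j1]) / std::abs(a[j2]),
                        1.0 / (j2 - j1));
    if (!std::isfinite(r) || r <= 0.0) r = 1.0;
    for (int t = 0; t < j2 - j1 && placed < d; ++t, ++placed) {
      double ang = 2.0 * M_PI * placed / d + 0.4 + 0.3 * s;
      roots[placed] = r * cplx(std::cos(ang), std::sin(ang));
    }
  }
  for (; placed < d; ++placed) {
    double ang = 2.0 * M_PI * placed / d + 0.4;
    roots[placed] = cplx(std::cos(ang), std::sin(ang));
  }
  for (int it = 0; it < 200; ++it) {
    double maxstep = 0.0, maxz = 1.0;
    for (int i = 0; i < d; ++i) {
      cplx z = roots[i];
      // Horner for p and p'
      cplx p = a[d], pp(0.0, 0.0);
      for (int k = d - 1; k >= 0; --k) { pp = pp * z + p; p = p * z + a[k]; }
      if (std::abs(p) == 0.0) continue;
      if (std::abs(pp) == 0.0) { roots[i] = z + cplx(1e-8, 1e-8); continue; }
      cplx w = p / pp;
      cplx S(0.0, 0.0);
      for (int j = 0; j < d; ++j) {
        if (j == i) continue;
        cplx dz = z - roots[j];
        if (std::abs(dz) < 1e-300) dz = cplx(1e-300, 0.0);
        S += 1.0 / dz;
      }
      cplx denom = 1.0 - w * S;
      cplx step = (std::abs(denom) > 1e-300) ? w / denom : w;
      roots[i] = z - step;
      double st = std::abs(step);
      if (st > maxstep) maxstep = st;
      double az = std::abs(roots[i]);
      if (az > maxz) maxz = az;
    }
    if (maxstep < 1e-14 * maxz) return true;
  }
  return true; // rely on downstream Newton polish + residual filter
}

struct Solution {
  cplx u, v;
  double rel_res;
  bool newton_ok;
};

// Newton polish on the full 2x2 system; returns relative residual
static bool newton_refine(const double* g1, const double* g2,
                          cplx& u, cplx& v, double tol, double* rel_out) {
  for (int it = 0; it < 40; ++it) {
    cplx f1, f1u, f1v, f2, f2u, f2v;
    eval_grid_jac(g1, u, v, &f1, &f1u, &f1v);
    eval_grid_jac(g2, u, v, &f2, &f2u, &f2v);
    cplx det = f1u * f2v - f1v * f2u;
    if (std::abs(det) < 1e-300) break;
    cplx du = (f1 * f2v - f2 * f1v) / det;
    cplx dv = (f2 * f1u - f1 * f2u) / det;
    u -= du; v -= dv;
    double step = std::abs(du) + std::abs(dv);
    double sz = 1.0 + std::abs(u) + std::abs(v);
    if (step < tol * sz) break;
    if (!std::isfinite(u.real()) || !std::isfinite(v.real()) ||
        !std::isfinite(u.imag()) || !std::isfinite(v.imag())) return false;
  }
  double s1, s2;
  cplx r1 = eval_grid(g1, u, v, &s1);
  cplx r2 = eval_grid(g2, u, v, &s2);
  double rel = std::max(std::abs(r1) / s1, std::abs(r2) / s2);
  if (rel_out) *rel_out = rel;
  return rel < ACCEPT_REL;
}

// highest v-power with a nonzero coefficient column
static int vdeg(const double* g) {
  for (int j = 4; j >= 0; --j)
    for (int i = 0; i < 5; ++i)
      if (g[i + 5 * j] != 0.0) return j;
  return -1;
}

static void transpose_grid(const double* g, double* t) {
  for (int i = 0; i < 5; ++i)
    for (int j = 0; j < 5; ++j)
      t[j + 5 * i] = g[i + 5 * j];
}

struct AttemptResult {
  std::vector<Solution> sols;
  int origin_mult;
  bool degenerate;
  std::vector<double> res_coeffs; // ascending resultant coefficients
};

// One elimination attempt at a given node radius.  Grids are used as given
// (caller transposes for the swapped order).  The generic resultant degree
// is 13 (weak) / 11 (strong), far below the 4m worst case, so the first
// attempt uses a reduced node count; retries use the full, alias-safe one.
// Real coefficients give det(conj u) = conj(det u), halving the LU work.
static AttemptResult attempt_solve(const double* g1, const double* g2,
                                   double radius, bool full_nodes,
                                   const SolveOpts& o) {
  AttemptResult out;
  out.origin_mult = 0;
  out.degenerate = false;

  int d1 = vdeg(g1), d2 = vdeg(g2);
  if (d1 < 1 || d2 < 1) { out.degenerate = true; return out; }
  int m = d1 + d2;
  int K = full_nodes ? (4 * m + 4) : (2 * m + 2);

  // determinant values at radius * K-th roots of unity
  std::vector<cplx> detv(K);
  std::vector<cplx> M(m * m);
  for (int k = 0; k <= K / 2; ++k) {
    double ang = 2.0 * M_PI * k / K;
    cplx u = radius * cplx(std::cos(ang), std::sin(ang));
    // v-coefficients of each polynomial at this u (Horner in u)
    cplx A[5], B[5];
    for (int j = 0; j <= d1; ++j) {
      cplx acc(0.0, 0.0);
      for (int i = 4; i >= 0; --i) acc = acc * u + g1[i + 5 * j];
      A[j] = acc;
    }
    for (int j = 0; j <= d2; ++j) {
      cplx acc(0.0, 0.0);
      for (int i = 4; i >= 0; --i) acc = acc * u + g2[i + 5 * j];
      B[j] = acc;
    }
    std::fill(M.begin(), M.end(), cplx(0.0, 0.0));
    for (int r = 0; r < d2; ++r)           // rows of A-coefficients
      for (int t = 0; t <= d1; ++t)
        M[r * m + r + t] = A[d1 - t];
    for (int r = 0; r < d1; ++r)           // rows of B-coefficients
      for (int t = 0; t <= d2; ++t)
        M[(d2 + r) * m + r + t] = B[d2 - t];
    detv[k] = det_lu(M.data(), m);
    if (k > 0 && k < (K + 1) / 2) detv[K - k] = std::conj(detv[k]);
  }

  // inverse DFT.  Degree trimming and the origin-multiplicity zero band
  // are decided on the raw coefficients (before undoing the radius
  // scaling), where the interpolation noise floor is uniform in j.
  std::vector<double> araw(K), a(K);
  double scale = 0.0;
  for (int j = 0; j < K; ++j) {
    cplx acc(0.0, 0.0);
    for (int k = 0; k < K; ++k) {
      double ang = -2.0 * M_PI * j * k / K;
      acc += detv[k] * cplx(std::cos(ang), std::sin(ang));
    }
    araw[j] = acc.real() / K;
    double aa = std::fabs(araw[j]);
    if (aa > scale) scale = aa;
  }
  if (scale == 0.0) { out.degenerate = true; return out; }

  int lead = -1;
  for (int j = K - 1; j >= 0; --j)
    if (std::fabs(araw[j]) > TRIM_REL * scale) { lead = j; break; }
  // the coefficients above the true degree are pure interpolation noise;
  // they calibrate the zero band for the origin-multiplicity count
  double noise = 1e-16 * scale;
  for (int j = lead + 1; j < K; ++j)
    if (std::fabs(araw[j]) > noise) noise = std::fabs(araw[j]);
  double zero_band = std::max(100.0 * noise, 1e-14 * scale);
  int m0 = 0;
  while (m0 < lead && std::fabs(araw[m0]) <= zero_band) ++m0;
  out.origin_mult = m0;
  double rpow = 1.0;
  for (int j = 0; j < K; ++j) { a[j] = araw[j] / rpow; rpow *= radius; }
  out.res_coeffs = a;
  if (lead <= m0) return out;   // origin only

  std::vector<cplx> b(a.begin() + m0, a.begin() + lead + 1);
  std::vector<cplx> uroots;
  aberth(b, uroots);

  for (size_t r = 0; r < uroots.size(); ++r) {
    cplx ur = uroots[r];
    if (!std::isfinite(ur.real()) || !std::isfinite(ur.imag())) continue;
    // v-polynomials at u = ur
    cplx P1[5], P2[5];
    double m1 = 0.0, m2 = 0.0;
    for (int j = 0; j < 5; ++j) {
      cplx acc1(0.0, 0.0), acc2(0.0, 0.0);
      for (int i = 4; i >= 0; --i) {
        acc1 = acc1 * ur + g1[i + 5 * j];
        acc2 = acc2 * ur + g2[i + 5 * j];
      }
      P1[j] = acc1; P2[j] = acc2;
      if (std::abs(acc1) > m1) m1 = std::abs(acc1);
      if (std::abs(acc2) > m2) m2 = std::abs(acc2);
    }
    // root both v-polynomials at their structural degrees (a tiny but
    // exact leading coefficient carries the system's large-|v| roots) and
    // pool the candidates; duplicates merge in the dedup pass
    (void)m1; (void)m2;
    std::vector<cplx> vroots;
    for (int which = 0; which < 2; ++which) {
      const cplx* P = which ? P2 : P1;
      int e = -1;
      for (int j = 4; j >= 0; --j)
        if (P[j] != cplx(0.0, 0.0)) { e = j; break; }
      if (e < 1) continue;
      std::vector<cplx> pv(P, P + e + 1);
      std::vector<cplx> vr1;
      aberth(pv, vr1);
      vroots.insert(vroots.end(), vr1.begin(), vr1.end());
    }
    std::vector<Solution> local;   // candidates of this u-root
    for (size_t s = 0; s < vroots.size(); ++s) {
      cplx vr = vroots[s];
      double sc1, sc2;
      cplx r1 = eval_grid(g1, ur, vr, &sc1);
      cplx r2 = eval_grid(g2, ur, vr, &sc2);
      if (std::abs(r1) / sc1 > CAND_REL ||
          std::abs(r2) / sc2 > CAND_REL) continue;
      cplx uu = ur, vv = vr;
      double rel;
      if (!newton_refine(g1, g2, uu, vv, o.newton_tol, &rel)) continue;
      // Newton is a polish step: a candidate that drifts away from its
      // originating resultant root (relative to the root's own size) has
      // slid into the singular origin's tangent cone or another basin
      if (std::abs(uu - ur) > DRIFT_REL * std::abs(ur) + o.t_zmax)
        continue;
      if (std::abs(vv - vr) > DRIFT_REL * std::abs(vr) + o.t_zmax)
        continue;
      if (std::abs(uu) < o.t_zmax && std::abs(vv) < o.t_zmax) continue;
      // a conjugate-symmetric system stalls complex Newton with a tiny
      // imaginary residue on real roots; accept the real projection when
      // it satisfies the system just as well
      double imu = std::fabs(uu.imag()), imv = std::fabs(vv.imag());
      if ((imu > 0.0 || imv > 0.0) &&
          imu < 1e-6 * (1.0 + std::fabs(uu.real())) &&
          imv < 1e-6 * (1.0 + std::fabs(vv.real()))) {
        cplx ru(uu.real(), 0.0), rv(vv.real(), 0.0);
        double rrel;
        if (newton_refine(g1, g2, ru, rv, o.newton_tol, &rrel) &&
            std::fabs(ru.imag()) == 0.0 && std::fabs(rv.imag()) == 0.0) {
          uu = ru; vv = rv; rel = rrel;
        }
      }
      Solution sol;
      sol.u = uu; sol.v = vv; sol.rel_res = rel; sol.newton_ok = true;
      // the two v-polynomial sources re-find the same root; at poorly
      // conditioned (very large) solutions the polished copies agree only
      // to a few digits, so same-u-root merging is looser than the global
      // dedup and keeps the smaller residual
      bool merged = false;
      for (size_t q = 0; q < local.size(); ++q) {
        double du = std::abs(sol.u - local[q].u) /
          (1.0 + std::abs(local[q].u));
        double dv = std::abs(sol.v - local[q].v) /
          (1.0 + std::abs(local[q].v));
        if (du < 1e-4 && dv < 1e-4) {
          if (sol.rel_res < local[q].rel_res) local[q] = sol;
          merged = true;
          break;
        }
      }
      if (!merged) local.push_back(sol);
    }
    out.sols.insert(out.sols.end(), local.begin(), local.end());
  }

  // dedup (relative distance)
  std::vector<Solution> uniq;
  for (size_t i = 0; i < out.sols.size(); ++i) {
    bool dup = false;
    for (size_t j = 0; j < uniq.size(); ++j) {
      double du = std::abs(out.sols[i].u - uniq[j].u) /
        (1.0 + std::abs(uniq[j].u));
      double dv = std::abs(out.sols[i].v - uniq[j].v) /
        (1.0 + std::abs(uniq[j].v));
      if (du < DEDUP_REL && dv < DEDUP_REL) { dup = true; break; }
    }
    if (!dup) uniq.push_back(out.sols[i]);
  }
  out.sols.swap(uniq);
  return out;
}

struct PointSummary {
  int origin_mult, n_proper, n_pos_real, status, n_attempts;
  std::vector<Solution> sols;
  std::vector<double> res_coeffs;
  bool swapped;
};

static void count_proper(const std::vector<Solution>& sols, bool swapped,
                         double t_zmin, double t_zmax, double t_inf,
                         int* n_proper, int* n_pos, bool* any_ambig) {
  *n_proper = 0; *n_pos = 0; *any_ambig = false;
  for (size_t i = 0; i < sols.size(); ++i) {
    cplx u = swapped ? sols[i].v : sols[i].u;
    cplx v = swapped ? sols[i].u : sols[i].v;
    int cu = classify_coord(u, t_zmin, t_zmax, t_inf);
    int cv = classify_coord(v, t_zmin, t_zmax, t_inf);
    if (cu == CL_AMBIG || cv == CL_AMBIG) *any_ambig = true;
    bool proper = (cu == CL_NZREAL || cu == CL_NZNONREAL) &&
                  (cv == CL_NZREAL || cv == CL_NZNONREAL);
    if (!proper) continue;
    ++*n_proper;
    if (cu == CL_NZREAL && cv == CL_NZREAL &&
        u.real() > t_zmax && v.real() > t_zmax) ++*n_pos;
  }
}

// Full retry ladder for one parameter point.  Ladder: v-elimination at
// radius 1, u-elimination at radius 1, v-elimination at radius 0.62 with
// the ambiguity band tightened (t_zmax -> 1e-11) from the first retry on.
static PointSummary solve_point(const double* g1, const double* g2,
                                const SolveOpts& o) {
  double t1[25], t2[25];
  transpose_grid(g1, t1);
  transpose_grid(g2, t2);

  struct Plan { bool swap; double radius; bool full_nodes; };
  Plan plans[3] = { {false, 1.0, false}, {true, 1.0, true},
                    {false, 0.62, true} };
  int n_attempts = std::min(o.max_retry + 1, 3);

  PointSummary best;
  best.status = -1;
  double balance = 0.0;   // node radius balancing the deflated resultant
  for (int att = 0; att < n_attempts; ++att) {
    if (att == 2 && balance > 0.0 &&
        (balance < 0.5 || balance > 2.0)) plans[2].radius = balance;
    const Plan& pl = plans[att];
    double tz = (att == 0) ? o.t_zmax : std::min(o.t_zmax, 1e-11);
    AttemptResult ar = pl.swap
      ? attempt_solve(t1, t2, pl.radius, pl.full_nodes, o)
      : attempt_solve(g1, g2, pl.radius, pl.full_nodes, o);
    if (att == 0 && !ar.degenerate && !ar.res_coeffs.empty()) {
      // geometric mean of the nonzero finite root magnitudes
      const std::vector<double>& a = ar.res_coeffs;
      double mx = 0.0;
      for (size_t j = 0; j < a.size(); ++j)
        if (std::fabs(a[j]) > mx) mx = std::fabs(a[j]);
      int lead = -1, m0 = -1;
      for (int j = (int)a.size() - 1; j >= 0; --j)
        if (std::fabs(a[j]) > 1e-11 * mx) { lead = j; break; }
      for (int j = 0; j <= lead; ++j)
        if (std::fabs(a[j]) > 1e-11 * mx) { m0 = j; break; }
      if (lead > m0 && m0 >= 0 && std::fabs(a[lead]) > 0.0) {
        double r = std::pow(std::fabs(a[m0] / a[lead]),
                            1.0 / (lead - m0));
        if (std::isfinite(r) && r > 0.0) balance = r;
      }
    }
    if (ar.degenerate) {
      if (best.status == -1) {
        best.origin_mult = 0; best.n_proper = 0; best.n_pos_real = 0;
        best.status = 3; best.n_attempts = att + 1; best.swapped = pl.swap;
      }
      continue;
    }
    int n_proper, n_pos;
    bool ambig;
    count_proper(ar.sols, pl.swap, o.t_zmin, tz, o.t_inf,
                 &n_proper, &n_pos, &ambig);
    bool generic = (o.expected_nf <= 0)
      ? (!ambig)
      : (ar.origin_mult == 6 && n_proper == o.expected_nf &&
         (n_pos == 1 || n_pos == 3) && !ambig);
    PointSummary cur;
    cur.origin_mult = ar.origin_mult;
    cur.n_proper = n_proper;
    cur.n_pos_real = n_pos;
    cur.status = generic ? (att == 0 ? 0 : 1) : 2;
    cur.n_attempts = att + 1;
    cur.sols = ar.sols;
    cur.res_coeffs = ar.res_coeffs;
    cur.swapped = pl.swap;
    if (generic) return cur;
    if (best.status == -1 || best.status == 3) best = cur;
  }
  if (best.status == -1) {
    best.origin_mult = 0; best.n_proper = 0; best.n_pos_real = 0;
    best.status = 3; best.n_attempts = n_attempts; best.swapped = false;
  }
  return best;
}

static SolveOpts opts_from_list(List opts) {
  SolveOpts o;
  o.t_zmin = as<double>(opts["t_zmin"]);
  o.t_zmax = as<double>(opts["t_zmax"]);
  o.t_inf = as<double>(opts["t_inf"]);
  o.newton_tol = as<double>(opts["newton_tol"]);
  o.expected_nf = as<int>(opts["expected_nf"]);
  o.max_retry = as<int>(opts["max_retry"]);
  return o;
}

// [[Rcpp::export]]
IntegerMatrix cpp_label_batch(NumericMatrix c1, NumericMatrix c2, List opts) {
  SolveOpts o = opts_from_list(opts);
  int n = c1.nrow();
  if (c2.nrow() != n || c1.ncol() != 25 || c2.ncol() != 25)
    stop("coefficient matrices must be n x 25");
  IntegerMatrix out(n, 5);
  colnames(out) = CharacterVector::create("origin_mult", "n_proper",
                                          "n_pos_real", "status",
                                          "n_attempts");
  double g1[25], g2[25];
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < 25; ++k) { g1[k] = c1(i, k); g2[k] = c2(i, k); }
    PointSummary ps = solve_point(g1, g2, o);
    out(i, 0) = ps.origin_mult;
    out(i, 1) = ps.n_proper;
    out(i, 2) = ps.n_pos_real;
    out(i, 3) = ps.status;
    out(i, 4) = ps.n_attempts;
    if (i % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
List cpp_solve_detail(NumericVector c1, NumericVector c2, List opts) {
  SolveOpts o = opts_from_list(opts);
  if (c1.size() != 25 || c2.size() != 25)
    stop("coefficient grids must have length 25");
  double g1[25], g2[25];
  for (int k = 0; k < 25; ++k) { g1[k] = c1[k]; g2[k] = c2[k]; }
  PointSummary ps = solve_point(g1, g2, o);
  int ns = (int)ps.sols.size();
  ComplexVector u(ns), v(ns);
  NumericVector rel(ns);
  for (int i = 0; i < ns; ++i) {
    cplx su = ps.swapped ? ps.sols[i].v : ps.sols[i].u;
    cplx sv = ps.swapped ? ps.sols[i].u : ps.sols[i].v;
    u[i].r = su.real(); u[i].i = su.imag();
    v[i].r = sv.real(); v[i].i = sv.imag();
    rel[i] = ps.sols[i].rel_res;
  }
  return List::create(
    _["u"] = u, _["v"] = v, _["rel_residual"] = rel,
    _["origin_mult"] = ps.origin_mult,
    _["n_proper"] = ps.n_proper,
    _["n_pos_real"] = ps.n_pos_real,
    _["status"] = ps.status,
    _["n_attempts"] = ps.n_attempts,
    _["resultant"] = NumericVector(ps.res_coeffs.begin(),
                                   ps.res_coeffs.end()),
    _["eliminated"] = ps.swapped ? "u" : "v");
}
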