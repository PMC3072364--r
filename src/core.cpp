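// Compiled kernels for the vertex model and the signaling integrator.
//
// Mesh encoding shared with R:
//   xy        V x 2 vertex positions
//   cell_idx  concatenated 0-based CCW vertex cycles
//   cell_ptr  length n_cells + 1 offsets into cell_idx
//   edges     E x 2 matrix of 0-based vertex ids
//   margin    logical per edge
//   lam_eff   per-edge effective tension scaling factor (lambda-bar_ij)
//
// Normalized energy: E = sum_e Lambda_e * lam_eff_e * l_e
//                      + sum_a 0.5 * (A_a - a_a)^2
//                      + sum_a (Gamma/2) * L_a^2
// with Lambda_e = lambda_bar (internal) or lambda_bar_margin (margin edges).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Mesh {
  const double *x, *y;
  int nv;
  const int *cidx, *cptr;
  int nc;
  const int *ev;  // edges column-major: ev[e], ev[e + ne]
  int ne;
  const int *marg;
  const double *lam;  // effective factor per edge
};

inline double cell_area(const Mesh &m, int a, const double *X, const double *Y) {
  double s = 0.0;
  int lo = m.cptr[a], hi = m.cptr[a + 1];
  for (int k = lo; k < hi; ++k) {
    int i = m.cidx[k];
    int j = m.cidx[(k + 1 < hi) ? k + 1 : lo];
    s += X[i] * Y[j] - X[j] * Y[i];
  }
  return 0.5 * s;
}

inline double cell_perim(const Mesh &m, int a, const double *X, const double *Y) {
  double s = 0.0;
  int lo = m.cptr[a], hi = m.cptr[a + 1];
  for (int k = lo; k < hi; ++k) {
    int i = m.cidx[k];
    int j = m.cidx[(k + 1 < hi) ? k + 1 : lo];
    double dx = X[j] - X[i], dy = Y[j] - Y[i];
    s += std::sqrt(dx * dx + dy * dy);
  }
  return s;
}

double energy_terms(const Mesh &m, const double *X, const double *Y,
                    double lambda_bar, double lambda_margin, double gamma_bar,
                    const double *target, double *out3) {
  double et = 0.0, ea = 0.0, ep = 0.0;
  for (int e = 0; e < m.ne; ++e) {
    int i = m.ev[e], j = m.ev[e + m.ne];
    double dx = X[j] - X[i], dy = Y[j] - Y[i];
    double L = m.marg[e] ? lambda_margin : lambda_bar;
    et += L * m.lam[e] * std::sqrt(dx * dx + dy * dy);
  }
  for (int a = 0; a < m.nc; ++a) {
    double A = cell_area(m, a, X, Y);
    double P = cell_perim(m, a, X, Y);
    double d = A - target[a];
    ea += 0.5 * d * d;
    ep += 0.5 * gamma_bar * P * P;
  }
  if (out3) { out3[0] = et; out3[1] = ea; out3[2] = ep; }
  return et + ea + ep;
}

void gradient(const Mesh &m, const double *X, const double *Y,
              double lambda_bar, double lambda_margin, double gamma_bar,
              const double *target, double *gx, double *gy) {
  for (int i = 0; i < m.nv; ++i) { gx[i] = 0.0; gy[i] = 0.0; }
  const double eps = 1e-300;
  for (int e = 0; e < m.ne; ++e) {
    int i = m.ev[e], j = m.ev[e + m.ne];
    double dx = X[j] - X[i], dy = Y[j] - Y[i];
    double l = std::sqrt(dx * dx + dy * dy) + eps;
    double c = (m.marg[e] ? lambda_margin : lambda_bar) * m.lam[e] / l;
    gx[i] -= c * dx; gy[i] -= c * dy;
    gx[j] += c * dx; gy[j] += c * dy;
  }
  for (int a = 0; a < m.nc; ++a) {
    int lo = m.cptr[a], hi = m.cptr[a + 1];
    int n = hi - lo;
    double A = cell_area(m, a, X, Y);
    double P = cell_perim(m, a, X, Y);
    double ka = A - target[a];
    double kp = gamma_bar * P;
    for (int k = 0; k < n; ++k) {
      int v = m.cidx[lo + k];
      int vp = m.cidx[lo + (k + n - 1) % n];
      int vn = m.cidx[lo + (k + 1) % n];
      // area term: dA/dx_v = (y_next - y_prev)/2 for CCW cycles
      gx[v] += ka * 0.5 * (Y[vn] - Y[vp]);
      gy[v] += ka * 0.5 * (X[vp] - X[vn]);
      // perimeter term
      double dxp = X[v] - X[vp], dyp = Y[v] - Y[vp];
      double lp = std::sqrt(dxp * dxp + dyp * dyp) + eps;
      double dxn = X[v] - X[vn], dyn = Y[v] - Y[vn];
      double ln = std::sqrt(dxn * dxn + dyn * dyn) + eps;
      gx[v] += kp * (dxp / lp + dxn / ln);
      gy[v] += kp * (dyp / lp + dyn / ln);
    }
  }
}

Mesh make_mesh(const NumericMatrix &xy, const IntegerVector &cell_idx,
               const IntegerVector &cell_ptr, const IntegerMatrix &edges,
               const IntegerVector &margin, const NumericVector &lam_eff) {
  Mesh m;
  m.x = &xy(0, 0);
  m.y = &xy(0, 1);
  m.nv = xy.nrow();
  m.cidx = cell_idx.begin();
  m.cptr = cell_ptr.begin();
  m.nc = cell_ptr.size() - 1;
  m.ev = edges.begin();
  m.ne = edges.nrow();
  m.marg = margin.begin();
  m.lam = lam_eff.begin();
  return m;
}

}  // namespace

// [[Rcpp::export]]
NumericVector vm_energy_cpp(NumericMatrix xy, IntegerVector cell_idx,
                            IntegerVector cell_ptr, IntegerMatrix edges,
                            IntegerVector margin, NumericVector lam_eff,
                            double lambda_bar, double lambda_margin,
                            double gamma_bar, NumericVector target) {
  Mesh m = make_mesh(xy, cell_idx, cell_ptr, edges, margin, lam_eff);
  std::vector<double> X(m.x, m.x + m.nv), Y(m.y, m.y + m.nv);
  double t3[3];
  double tot = energy_terms(m, X.data(), Y.data(), lambda_bar, lambda_margin,
                            gamma_bar, target.begin(), t3);
  return NumericVector::create(_["tension"] = t3[0], _["area"] = t3[1],
                               _["perimeter"] = t3[2], _["total"] = tot);
}

// [[Rcpp::export]]
NumericMatrix vm_gradient_cpp(NumericMatrix xy, IntegerVector cell_idx,
                              IntegerVector cell_ptr, IntegerMatrix edges,
                              IntegerVector margin, NumericVector lam_eff,
                              double lambda_bar, double lambda_margin,
                              double gamma_bar, NumericVector target) {
  Mesh m = make_mesh(xy, cell_idx, cell_ptr, edges, margin, lam_eff);
  std::vector<double> X(m.x, m.x + m.nv), Y(m.y, m.y + m.nv);
  NumericMatrix g(m.nv, 2);
  std::vector<double> gx(m.nv), gy(m.nv);
  gradient(m, X.data(), Y.data(), lambda_bar, lambda_margin, gamma_bar,
           target.begin(), gx.data(), gy.data());
  for (int i = 0; i < m.nv; ++i) { g(i, 0) = gx[i]; g(i, 1) = gy[i]; }
  return g;
}

// Quasi-Newton (limited-memory BFGS) minimization of the vertex energy
// with Armijo backtracking line search; curvature pairs with non-positive
// s.y are skipped so the inverse-Hessian approximation stays positive
// definite. Convergence criterion is max |gradient component| < tol.
// [[Rcpp::export]]
List vm_relax_cpp(NumericMatrix xy, IntegerVector cell_idx,
                  IntegerVector cell_ptr, IntegerMatrix edges,
                  IntegerVector margin, NumericVector lam_eff,
                  double lambda_bar, double lambda_margin, double gamma_bar,
                  NumericVector target, double tol, int maxit,
                  Nullable<IntegerVector> free_mask = R_NilValue) {
  Mesh m = make_mesh(xy, cell_idx, cell_ptr, edges, margin, lam_eff);
  int nv = m.nv;
  int n = 2 * nv;
  std::vector<double> x(n), g(n), g1(n), d(n), xt(n);
  for (int i = 0; i < nv; ++i) { x[i] = m.x[i]; x[nv + i] = m.y[i]; }
  const double *tg = target.begin();
  // optional restriction to a subset of movable vertices (local relaxation
  // around a perturbation); fixed vertices have their gradient masked out
  std::vector<char> mv(n, 1);
  if (free_mask.isNotNull()) {
    IntegerVector fm(free_mask);
    for (int i = 0; i < nv; ++i) {
      mv[i] = mv[nv + i] = fm[i] ? 1 : 0;
    }
  }
  auto mask = [&](std::vector<double> &v) {
    for (int i = 0; i < n; ++i) {
      if (!mv[i]) v[i] = 0.0;
    }
  };

  const int mem = 8;
  std::vector<std::vector<double>> S(mem, std::vector<double>(n)),
      Yv(mem, std::vector<double>(n));
  std::vector<double> rho(mem);
  int nstored = 0, newest = -1;

  auto fval = [&](const double *v) {
    return energy_terms(m, v, v + nv, lambda_bar, lambda_margin, gamma_bar,
                        tg, nullptr);
  };
  auto fgrad = [&](const double *v, double *out) {
    gradient(m, v, v + nv, lambda_bar, lambda_margin, gamma_bar, tg, out,
             out + nv);
  };

  double f = fval(x.data());
  fgrad(x.data(), g.data());
  mask(g);
  double gmax = 0.0;
  for (int i = 0; i < n; ++i) gmax = std::max(gmax, std::fabs(g[i]));
  bool converged = gmax < tol;
  int it = 0;
  int tiny_steps = 0;
  const double c1 = 1e-4;
  std::vector<double> alpha(mem);

  while (!converged && it < maxit) {
    ++it;
    // two-loop recursion: d = -H g
    for (int i = 0; i < n; ++i) d[i] = g[i];
    double gamma = 1.0;
    for (int k = 0; k < nstored; ++k) {
      int idx = (newest - k + mem) % mem;
      double sq = 0.0;
      for (int i = 0; i < n; ++i) sq += S[idx][i] * d[i];
      alpha[idx] = rho[idx] * sq;
      for (int i = 0; i < n; ++i) d[i] -= alpha[idx] * Yv[idx][i];
    }
    if (nstored > 0) {
      double sy = 0.0, yy = 0.0;
      for (int i = 0; i < n; ++i) {
        sy += S[newest][i] * Yv[newest][i];
        yy += Yv[newest][i] * Yv[newest][i];
      }
      if (yy > 0) gamma = sy / yy;
    }
    for (int i = 0; i < n; ++i) d[i] *= gamma;
    for (int k = nstored - 1; k >= 0; --k) {
      int idx = (newest - k + mem) % mem;
      double yq = 0.0;
      for (int i = 0; i < n; ++i) yq += Yv[idx][i] * d[i];
      double beta = rho[idx] * yq;
      for (int i = 0; i < n; ++i) d[i] += S[idx][i] * (alpha[idx] - beta);
    }
    for (int i = 0; i < n; ++i) d[i] = -d[i];

    double gd = 0.0;
    for (int i = 0; i < n; ++i) gd += g[i] * d[i];
    if (gd >= 0) {  // reset to steepest descent
      nstored = 0;
      double gg = 0.0;
      for (int i = 0; i < n; ++i) { d[i] = -g[i]; gg += g[i] * g[i]; }
      gd = -gg;
    }

    double t = (it == 1 && nstored == 0)
                   ? std::min(1.0, 0.1 / std::max(gmax, 1e-12))
                   : 1.0;
    bool ok = false;
    double fnew = f;
    for (int ls = 0; ls < 30; ++ls) {
      for (int i = 0; i < n; ++i) xt[i] = x[i] + t * d[i];
      fnew = fval(xt.data());
      if (fnew <= f + c1 * t * gd) { ok = true; break; }
      t *= 0.5;
    }
    if (!ok) break;                      // numerical floor reached
    if (t < 1e-9 && ++tiny_steps > 5) break;  // thrashing near a kink
    fgrad(xt.data(), g1.data());
    mask(g1);
    // store curvature pair
    int slot = (newest + 1) % mem;
    double sy = 0.0, ss = 0.0, yy2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double si = xt[i] - x[i];
      double yi = g1[i] - g[i];
      S[slot][i] = si;
      Yv[slot][i] = yi;
      sy += si * yi;
      ss += si * si;
      yy2 += yi * yi;
    }
    if (sy > 1e-12 * std::sqrt(ss * yy2)) {
      newest = slot;
      rho[slot] = 1.0 / sy;
      if (nstored < mem) ++nstored;
    }
    x.swap(xt);
    f = fnew;
    g.swap(g1);
    gmax = 0.0;
    for (int i = 0; i < n; ++i) gmax = std::max(gmax, std::fabs(g[i]));
    converged = gmax < tol;
  }

  NumericMatrix out(nv, 2);
  for (int i = 0; i < nv; ++i) { out(i, 0) = x[i]; out(i, 1) = x[nv + i]; }
  return List::create(_["xy"] = out, _["energy"] = f, _["niter"] = it,
                      _["gmax"] = gmax, _["converged"] = converged);
}

// Areas, perimeters and area centroids of all cells in one pass.
// [[Rcpp::export]]
List cell_geom_cpp(NumericMatrix xy, IntegerVector cell_idx,
                   IntegerVector cell_ptr) {
  int nc = cell_ptr.size() - 1;
  NumericVector area(nc), perim(nc);
  NumericMatrix ctr(nc, 2);
  const int *cidx = cell_idx.begin();
  const int *cptr = cell_ptr.begin();
  for (int a = 0; a < nc; ++a) {
    int lo = cptr[a], hi = cptr[a + 1];
    double s = 0.0, p = 0.0, cx = 0.0, cy = 0.0, mx = 0.0, my = 0.0;
    int cnt = hi - lo;
    for (int k = lo; k < hi; ++k) {
      int i = cidx[k];
      int j = cidx[(k + 1 < hi) ? k + 1 : lo];
      double xi = xy(i, 0), yi = xy(i, 1), xj = xy(j, 0), yj = xy(j, 1);
      double cr = xi * yj - xj * yi;
      s += cr;
      cx += (xi + xj) * cr;
      cy += (yi + yj) * cr;
      p += std::sqrt((xj - xi) * (xj - xi) + (yj - yi) * (yj - yi));
      mx += xi;
      my += yi;
    }
    double A = 0.5 * s;
    area[a] = A;
    perim[a] = p;
    if (std::fabs(A) < 1e-300) {
      ctr(a, 0) = mx / cnt;
      ctr(a, 1) = my / cnt;
    } else {
      ctr(a, 0) = cx / (6.0 * A);
      ctr(a, 1) = cy / (6.0 * A);
    }
  }
  return List::create(_["area"] = area, _["perimeter"] = perim,
                      _["centroid"] = ctr);
}

// ---------------------------------------------------------------------------
// Signaling: operator-split finite-volume diffusion of Hh + per-cell
// mass-action kinetics (RK4), marched to quasi-steady state.
//
// Parameter vector kp (fixed order):
//  0 D          1 rho_Hh_P    2 k_on       3 k_off      4 rho_Ptc_basal_A
//  5 k_Ptc_Smo_A 6 rho_Smo    7 rho_Lx     8 k_pump     9 k_f
// 10 k_r       11 rho_TMx_basal 12 k_TMx_Smo_A
// 13..19 delta_{Hh,Ptc,HhPtc,Smo,Lx,LxSmo,TMx}

namespace {

inline void kin_rhs(const double *c, bool isA, double g, const double *kp,
                    double *dc) {
  double Hh = c[0], Ptc = c[1], HhPtc = c[2], Smo = c[3], Lx = c[4],
         LxSmo = c[5], TMx = c[6];
  double bind = kp[2] * Hh * Ptc - kp[3] * HhPtc;   // k_on Hh Ptc - k_off HhPtc
  double assoc = kp[9] * Lx * Smo - kp[10] * LxSmo; // k_f Lx Smo - k_r LxSmo
  dc[0] = (isA ? 0.0 : kp[1]) - bind - kp[13] * Hh;
  dc[1] = (isA ? kp[4] + kp[5] * LxSmo : 0.0) - bind - kp[14] * Ptc;
  dc[2] = bind - kp[15] * HhPtc;
  dc[3] = kp[6] * g - assoc - kp[16] * Smo;
  dc[4] = kp[7] - assoc - kp[8] * Ptc * Lx - kp[17] * Lx;
  dc[5] = assoc - kp[18] * LxSmo;
  dc[6] = kp[11] + (isA ? kp[12] * LxSmo : 0.0) - kp[19] * TMx;
}

// Jacobian of the kinetics right-hand side (column-major 7x7).
inline void kin_jac(const double *c, bool isA, const double *kp, double *J) {
  for (int i = 0; i < 49; ++i) J[i] = 0.0;
  double Hh = c[0], Ptc = c[1], Smo = c[3], Lx = c[4];
  double kon = kp[2], koff = kp[3], kf = kp[9], kr = kp[10], kpump = kp[8];
#define JAC(r, cidx) J[(r) + 7 * (cidx)]
  JAC(0, 0) = -kon * Ptc - kp[13];
  JAC(0, 1) = -kon * Hh;
  JAC(0, 2) = koff;
  JAC(1, 0) = -kon * Ptc;
  JAC(1, 1) = -kon * Hh - kp[14];
  JAC(1, 2) = koff;
  if (isA) JAC(1, 5) = kp[5];
  JAC(2, 0) = kon * Ptc;
  JAC(2, 1) = kon * Hh;
  JAC(2, 2) = -koff - kp[15];
  JAC(3, 3) = -kf * Lx - kp[16];
  JAC(3, 4) = -kf * Smo;
  JAC(3, 5) = kr;
  JAC(4, 1) = -kpump * Lx;
  JAC(4, 3) = -kf * Lx;
  JAC(4, 4) = -kf * Smo - kpump * Ptc - kp[17];
  JAC(4, 5) = kr;
  JAC(5, 3) = kf * Lx;
  JAC(5, 4) = kf * Smo;
  JAC(5, 5) = -kr - kp[18];
  if (isA) JAC(6, 5) = kp[12];
  JAC(6, 6) = -kp[19];
#undef JAC
}

// Solve the 7x7 system A x = b in place (partial pivoting); returns false
// on a singular matrix.
inline bool solve7(double *A, double *b) {
  const int n = 7;
  for (int k = 0; k < n; ++k) {
    int piv = k;
    double best = std::fabs(A[k + n * k]);
    for (int i = k + 1; i < n; ++i) {
      double v = std::fabs(A[i + n * k]);
      if (v > best) { best = v; piv = i; }
    }
    if (best < 1e-14) return false;
    if (piv != k) {
      for (int j = 0; j < n; ++j) std::swap(A[k + n * j], A[piv + n * j]);
      std::swap(b[k], b[piv]);
    }
    for (int i = k + 1; i < n; ++i) {
      double f = A[i + n * k] / A[k + n * k];
      if (f == 0.0) continue;
      for (int j = k; j < n; ++j) A[i + n * j] -= f * A[k + n * j];
      b[i] -= f * b[k];
    }
  }
  for (int i = n - 1; i >= 0; --i) {
    double s = b[i];
    for (int j = i + 1; j < n; ++j) s -= A[i + n * j] * b[j];
    b[i] = s / A[i + n * i];
  }
  return true;
}

// Solve the implicit stage equation x = b + h f(x) by Newton iteration
// (the kinetics are stiff: the Ptc-dependent Lx pump is much faster than
// the decay rates). `x` holds the initial guess on entry and the solution
// on success.
inline bool stage_solve(double *x, const double *b, bool isA, double g,
                        const double *kp, double h) {
  for (int it = 0; it < 25; ++it) {
    double f[7], J[49], r[7];
    kin_rhs(x, isA, g, kp, f);
    double rn = 0.0;
    for (int s = 0; s < 7; ++s) {
      r[s] = x[s] - b[s] - h * f[s];
      rn = std::max(rn, std::fabs(r[s]));
    }
    if (rn < 1e-11 * (1.0 + h)) return true;
    kin_jac(x, isA, kp, J);
    double M[49];
    for (int i = 0; i < 7; ++i) {
      for (int j = 0; j < 7; ++j) {
        M[i + 7 * j] = (i == j ? 1.0 : 0.0) - h * J[i + 7 * j];
      }
    }
    if (!solve7(M, r)) return false;
    for (int s = 0; s < 7; ++s) x[s] -= r[s];
  }
  return false;
}

// One L-stable second-order SDIRK step of the kinetics (two implicit
// stages with gamma = 1 - sqrt(2)/2; stiffly accurate). Returns false if
// either Newton solve fails or negativity beyond roundoff appears.
inline bool be_cell(double *c, bool isA, double g, const double *kp,
                    double dt) {
  const double gam = 1.0 - std::sqrt(2.0) / 2.0;
  double x1[7], x2[7], b[7], f1[7];
  for (int s = 0; s < 7; ++s) x1[s] = c[s];
  if (!stage_solve(x1, c, isA, g, kp, gam * dt)) return false;
  kin_rhs(x1, isA, g, kp, f1);
  for (int s = 0; s < 7; ++s) {
    b[s] = c[s] + (1.0 - gam) * dt * f1[s];
    x2[s] = x1[s];
  }
  if (!stage_solve(x2, b, isA, g, kp, gam * dt)) return false;
  for (int s = 0; s < 7; ++s) {
    if (x2[s] < 0) {
      if (x2[s] < -1e-8) return false;
      x2[s] = 0.0;
    }
  }
  for (int s = 0; s < 7; ++s) c[s] = x2[s];
  return true;
}

}  // namespace

// Advance the full signaling system (diffusion + kinetics) until the maximum
// relative rate of change per unit time drops below tol, or until t_max.
// [[Rcpp::export]]
List signal_advance_cpp(NumericMatrix conc, IntegerVector comp,
                        IntegerVector geno, NumericVector areas,
                        IntegerMatrix iedges, NumericVector w_over_d,
                        NumericVector kp, double tol, double t_max,
                        int check_every, double dt_macro_max) {
  int n = conc.nrow();
  int ne = iedges.nrow();
  double D = kp[0];
  NumericMatrix C = clone(conc);

  std::vector<double> gmul(n);
  std::vector<bool> isA(n);
  for (int a = 0; a < n; ++a) {
    isA[a] = comp[a] == 1;
    gmul[a] = geno[a] == 0 ? 1.0 : (geno[a] == 1 ? 0.0 : 2.0);
  }

  std::vector<double> prev(n * 7);
  double t = 0.0;
  bool converged = false;
  double max_rate = R_PosInf;

  // Strang splitting per macro step: explicit finite-volume diffusion for
  // dt/2 (substepped inside the stability bound), one implicit
  // (backward-Euler/Newton) kinetics step of dt, diffusion for dt/2.
  // Second-order in the splitting, and the steady state of each subflow is
  // exact, so the composed fixed point converges fast in dt.
  double dt_macro = std::min(dt_macro_max, t_max);
  // Implicit finite-volume diffusion by the TR-BDF2 composite scheme
  // (L-stable, second order). Both stages solve SPD systems
  //   (W + c * D * L) x = rhs
  // with W = diag(cell areas) and L the weighted graph Laplacian, by
  // Jacobi-preconditioned conjugate gradient. Unconditionally stable,
  // conserves total amount exactly (column sums of L vanish), and immune
  // to the tiny stability bounds degenerate cells would force on an
  // explicit scheme.
  std::vector<double> cg_x(n), cg_r(n), cg_z(n), cg_p(n), cg_Ap(n),
      cg_diag(n), rhs(n), h0(n), hstar(n);
  auto apply_L = [&](const std::vector<double> &x, std::vector<double> &out) {
    std::fill(out.begin(), out.end(), 0.0);
    for (int e = 0; e < ne; ++e) {
      int a = iedges(e, 0), b = iedges(e, 1);
      double q = D * w_over_d[e] * (x[a] - x[b]);
      out[a] += q;
      out[b] -= q;
    }
  };
  // solve (W + c L) x = rhs, warm-started from x
  auto solve_spd = [&](double c, const std::vector<double> &b,
                       std::vector<double> &x) {
    for (int a = 0; a < n; ++a) cg_diag[a] = areas[a];
    for (int e = 0; e < ne; ++e) {
      double w = c * D * w_over_d[e];
      cg_diag[iedges(e, 0)] += w;
      cg_diag[iedges(e, 1)] += w;
    }
    apply_L(x, cg_Ap);
    double bnorm = 0.0;
    for (int a = 0; a < n; ++a) {
      cg_r[a] = b[a] - areas[a] * x[a] - c * cg_Ap[a];
      bnorm = std::max(bnorm, std::fabs(b[a]));
    }
    double rz = 0.0;
    for (int a = 0; a < n; ++a) {
      cg_z[a] = cg_r[a] / cg_diag[a];
      cg_p[a] = cg_z[a];
      rz += cg_r[a] * cg_z[a];
    }
    double tol_abs = 1e-12 * std::max(bnorm, 1e-30);
    for (int it = 0; it < 1000; ++it) {
      double rmax = 0.0;
      for (int a = 0; a < n; ++a) rmax = std::max(rmax, std::fabs(cg_r[a]));
      if (rmax < tol_abs) break;
      apply_L(cg_p, cg_Ap);
      double pAp = 0.0;
      for (int a = 0; a < n; ++a) {
        cg_Ap[a] = areas[a] * cg_p[a] + c * cg_Ap[a];
        pAp += cg_p[a] * cg_Ap[a];
      }
      if (pAp <= 0) break;
      double alpha = rz / pAp;
      for (int a = 0; a < n; ++a) {
        x[a] += alpha * cg_p[a];
        cg_r[a] -= alpha * cg_Ap[a];
      }
      double rz_new = 0.0;
      for (int a = 0; a < n; ++a) {
        cg_z[a] = cg_r[a] / cg_diag[a];
        rz_new += cg_r[a] * cg_z[a];
      }
      double beta = rz_new / rz;
      rz = rz_new;
      for (int a = 0; a < n; ++a) cg_p[a] = cg_z[a] + beta * cg_p[a];
    }
  };
  const double trb_g = 2.0 - std::sqrt(2.0);
  const double trb_a1 = 1.0 / (trb_g * (2.0 - trb_g));
  const double trb_a2 = -(1.0 - trb_g) * (1.0 - trb_g) / (trb_g * (2.0 - trb_g));
  const double trb_c2 = (1.0 - trb_g) / (2.0 - trb_g);
  // explicit stability bound, for choosing the cheap path below
  double dt_diff = R_PosInf;
  {
    std::vector<double> wsum(n, 0.0);
    for (int e = 0; e < ne; ++e) {
      wsum[iedges(e, 0)] += D * w_over_d[e];
      wsum[iedges(e, 1)] += D * w_over_d[e];
    }
    for (int a = 0; a < n; ++a) {
      if (wsum[a] > 0) dt_diff = std::min(dt_diff, areas[a] / wsum[a]);
    }
  }
  auto diffuse_for = [&](double dtt) {
    if (ne == 0) return;
    int nsub = R_finite(dt_diff)
                   ? (int)std::ceil(dtt / (0.9 * dt_diff))
                   : 1;
    if (nsub <= 8) {
      // healthy mesh: explicit Heun (RK2) substeps are cheapest
      double dts = dtt / nsub;
      for (int sub = 0; sub < nsub; ++sub) {
        for (int a = 0; a < n; ++a) h0[a] = C(a, 0);
        apply_L(h0, cg_Ap);
        for (int a = 0; a < n; ++a) {
          hstar[a] = h0[a] - dts / areas[a] * cg_Ap[a];
          rhs[a] = cg_Ap[a];  // keep first-stage rate
        }
        apply_L(hstar, cg_Ap);
        for (int a = 0; a < n; ++a) {
          C(a, 0) = h0[a] - 0.5 * dts / areas[a] * (rhs[a] + cg_Ap[a]);
        }
      }
      return;
    }
    // degenerate geometry somewhere: fall back to L-stable TR-BDF2
    for (int a = 0; a < n; ++a) h0[a] = C(a, 0);
    apply_L(h0, cg_Ap);
    double c1 = trb_g * dtt / 2.0;
    for (int a = 0; a < n; ++a) rhs[a] = areas[a] * h0[a] - c1 * cg_Ap[a];
    hstar = h0;  // warm start
    solve_spd(c1, rhs, hstar);
    double c2 = trb_c2 * dtt;
    for (int a = 0; a < n; ++a) {
      rhs[a] = areas[a] * (trb_a1 * hstar[a] + trb_a2 * h0[a]);
    }
    cg_x = hstar;  // warm start
    solve_spd(c2, rhs, cg_x);
    for (int a = 0; a < n; ++a) C(a, 0) = cg_x[a];
  };
  while (t < t_max && !converged) {
    for (int a = 0; a < n; ++a) {
      for (int s = 0; s < 7; ++s) prev[a * 7 + s] = C(a, s);
    }
    double tblock = 0.0;
    for (int step = 0; step < check_every && t + tblock < t_max; ++step) {
      diffuse_for(dt_macro / 2.0);
      for (int a = 0; a < n; ++a) {
        double c[7];
        for (int s = 0; s < 7; ++s) c[s] = C(a, s);
        if (!be_cell(c, isA[a], gmul[a], kp.begin(), dt_macro)) {
          // halve the implicit step a few times before giving up
          bool ok = false;
          for (int halves = 1; halves <= 4 && !ok; ++halves) {
            for (int s = 0; s < 7; ++s) c[s] = C(a, s);
            int nsteps = 1 << halves;
            ok = true;
            for (int k = 0; k < nsteps && ok; ++k) {
              ok = be_cell(c, isA[a], gmul[a], kp.begin(),
                           dt_macro / nsteps);
            }
          }
          if (!ok) stop("kinetics step failed after step-size reduction");
        }
        for (int s = 0; s < 7; ++s) C(a, s) = c[s];
      }
      diffuse_for(dt_macro / 2.0);
      tblock += dt_macro;
    }
    t += tblock;
    if (tblock <= 0) break;
    max_rate = 0.0;
    for (int a = 0; a < n; ++a) {
      for (int s = 0; s < 7; ++s) {
        double rate = std::fabs(C(a, s) - prev[a * 7 + s]) /
                      (tblock * (std::fabs(C(a, s)) + 0.01));
        max_rate = std::max(max_rate, rate);
      }
    }
    converged = max_rate < tol;
  }

  return List::create(_["conc"] = C, _["t"] = t, _["converged"] = converged,
                      _["max_rate"] = max_rate);
}
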