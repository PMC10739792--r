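// Planar musculoskeletal walker core.
//
// Rigid-body tree in the sagittal plane (x forward, y up, rotations about +z,
// radians), Hill-type muscle-tendon units integrated at the physics substep,
// penalty ground contact with regularised Coulomb friction. Everything here
// is deterministic; all randomness lives on the R side.
//
// Conventions:
//   * generalized coordinates q = (base x, base y, trunk pitch, joint angles...)
//   * moment arm r = dL/dtheta (L = MTU path length); the generalized force of
//     a muscle with tension F on joint dof d is therefore -F * r_d.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Hill curve primitives. Constant vector cc layout:
//   [0] gamma     active force-length Gaussian width           (0.45)
//   [1] e0_pass   passive fiber strain at which f_pass = 1     (0.6)
//   [2] kpe       passive exponential shape                    (4)
//   [3] a_hill    Hill hyperbola curvature a/F0                (0.25)
//   [4] fv_plat   eccentric plateau                            (1.4)
//   [5] eps0      tendon strain at F0                          (0.049)
//   [6] toe_frac  tendon toe-region end as fraction of eps0    (0.4)

static inline double act_fl(double x, const double* cc) {
  double d = x - 1.0;
  return std::exp(-d * d / cc[0]);
}
static inline double act_fl_d(double x, const double* cc) {
  return act_fl(x, cc) * (-2.0 * (x - 1.0) / cc[0]);
}
static inline double pas_fl(double x, const double* cc) {
  if (x <= 1.0) return 0.0;
  return (std::exp(cc[2] * (x - 1.0) / cc[1]) - 1.0) / (std::exp(cc[2]) - 1.0);
}
static inline double pas_fl_d(double x, const double* cc) {
  if (x <= 1.0) return 0.0;
  return (cc[2] / cc[1]) * std::exp(cc[2] * (x - 1.0) / cc[1]) /
         (std::exp(cc[2]) - 1.0);
}
static inline double fv_curve(double x, const double* cc) {
  double a = cc[3], p = cc[4];
  if (x <= -1.0) return 0.0;
  if (x < 0.0) return (1.0 + x) / (1.0 - x / a);
  double s = (1.0 + 1.0 / a) / (p - 1.0);  // C1 join at x = 0
  return p - (p - 1.0) * std::exp(-s * x);
}
static inline double fv_inverse(double m, const double* cc) {
  double a = cc[3], p = cc[4];
  if (m <= 0.0) return -1.0;
  if (m < 1.0) return (m - 1.0) / (1.0 + m / a);
  double s = (1.0 + 1.0 / a) / (p - 1.0);
  double mm = std::min(m, p - 1e-4);
  return -std::log((p - mm) / (p - 1.0)) / s;
}
static inline double ten_fl(double e, const double* cc) {
  if (e <= 0.0) return 0.0;
  double et = cc[6] * cc[5];
  double klin = 1.0 / (cc[5] - 0.5 * et);
  if (e < et) return klin * e * e / (2.0 * et);
  return klin * (e - 0.5 * et);
}
static inline double ten_fl_d(double e, const double* cc) {
  if (e <= 0.0) return 0.0;
  double et = cc[6] * cc[5];
  double klin = 1.0 / (cc[5] - 0.5 * et);
  return (e < et) ? klin * e / et : klin;
}

// [[Rcpp::export]]
NumericVector cpp_curve(int kind, NumericVector x, NumericVector cc) {
  const double* c = cc.begin();
  int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    switch (kind) {
      case 1: out[i] = act_fl(x[i], c); break;
      case 2: out[i] = pas_fl(x[i], c); break;
      case 3: out[i] = fv_curve(x[i], c); break;
      case 4: out[i] = ten_fl(x[i], c); break;
      default: stop("unknown curve kind");
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_curve_d(int kind, NumericVector x, NumericVector cc) {
  const double* c = cc.begin();
  int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    switch (kind) {
      case 1: out[i] = act_fl_d(x[i], c); break;
      case 2: out[i] = pas_fl_d(x[i], c); break;
      case 4: out[i] = ten_fl_d(x[i], c); break;
      default: stop("no analytic derivative for this curve kind");
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_fv_inverse(NumericVector m, NumericVector cc) {
  const double* c = cc.begin();
  NumericVector out(m.size());
  for (int i = 0; i < m.size(); ++i) out[i] = fv_inverse(m[i], c);
  return out;
}

// ---------------------------------------------------------------------------
// Model core accessors (built by model_core() on the R side; segments are
// ordered parents-first, segment 0 is the floating trunk).

struct Core {
  int ns, nm, ndof, nj, nsph, neff;
  IntegerVector seg_parent, seg_dof;
  NumericVector seg_sign, mass, inertia;
  NumericMatrix anchor, com;     // 2 x ns, local coords
  IntegerVector mus_ptr, mus_seg;
  NumericMatrix mus_xy;          // 2 x total path points
  NumericVector F0, lopt, lslack, penn, vmax, tact, tdeact;
  IntegerVector sph_seg, sph_foot, sph_heel;
  NumericMatrix sph_xy;
  NumericVector sph_r;
  NumericVector jlim_lo, jlim_hi;
  double jlim_k, jlim_c, joint_damp;
  double kn, cn, veps, grav, act_min, mus_beta;
  IntegerVector dof_free;
  NumericVector cc;
  IntegerVector eff_seg;
  NumericMatrix eff_xy;

  explicit Core(const List& L)
      : seg_parent(as<IntegerVector>(L["seg_parent"])),
        seg_dof(as<IntegerVector>(L["seg_dof"])),
        seg_sign(as<NumericVector>(L["seg_sign"])),
        mass(as<NumericVector>(L["mass"])),
        inertia(as<NumericVector>(L["inertia"])),
        anchor(as<NumericMatrix>(L["anchor"])),
        com(as<NumericMatrix>(L["com"])),
        mus_ptr(as<IntegerVector>(L["mus_ptr"])),
        mus_seg(as<IntegerVector>(L["mus_seg"])),
        mus_xy(as<NumericMatrix>(L["mus_xy"])),
        F0(as<NumericVector>(L["F0"])),
        lopt(as<NumericVector>(L["lopt"])),
        lslack(as<NumericVector>(L["lslack"])),
        penn(as<NumericVector>(L["penn"])),
        vmax(as<NumericVector>(L["vmax"])),
        tact(as<NumericVector>(L["tau_act"])),
        tdeact(as<NumericVector>(L["tau_deact"])),
        sph_seg(as<IntegerVector>(L["sph_seg"])),
        sph_foot(as<IntegerVector>(L["sph_foot"])),
        sph_heel(as<IntegerVector>(L["sph_heel"])),
        sph_xy(as<NumericMatrix>(L["sph_xy"])),
        sph_r(as<NumericVector>(L["sph_r"])),
        jlim_lo(as<NumericVector>(L["jlim_lo"])),
        jlim_hi(as<NumericVector>(L["jlim_hi"])),
        dof_free(as<IntegerVector>(L["dof_free"])),
        cc(as<NumericVector>(L["curve_constants"])),
        eff_seg(as<IntegerVector>(L["eff_seg"])),
        eff_xy(as<NumericMatrix>(L["eff_xy"])) {
    ns = seg_parent.size();
    nm = F0.size();
    ndof = dof_free.size();
    nj = ndof - 3;
    nsph = sph_seg.size();
    neff = eff_seg.size();
    jlim_k = as<double>(L["jlim_k"]);
    jlim_c = as<double>(L["jlim_c"]);
    joint_damp = as<double>(L["joint_damp"]);
    kn = as<double>(L["contact_kn"]);
    cn = as<double>(L["contact_cn"]);
    veps = as<double>(L["contact_veps"]);
    grav = as<double>(L["gravity"]);
    act_min = as<double>(L["act_min"]);
    mus_beta = as<double>(L["mus_beta"]);
  }
};

struct Frames {
  std::vector<double> w, ox, oy, wd;
};

static void fk(const Core& C, const double* q, const double* qd, Frames& F) {
  F.w.assign(C.ns, 0.0);
  F.ox.assign(C.ns, 0.0);
  F.oy.assign(C.ns, 0.0);
  F.wd.assign(C.ns, 0.0);
  F.w[0] = q[2];
  F.ox[0] = q[0];
  F.oy[0] = q[1];
  F.wd[0] = qd ? qd[2] : 0.0;
  for (int s = 1; s < C.ns; ++s) {
    int p = C.seg_parent[s];
    double cw = std::cos(F.w[p]), sw = std::sin(F.w[p]);
    double ax = C.anchor(0, s), ay = C.anchor(1, s);
    F.ox[s] = F.ox[p] + cw * ax - sw * ay;
    F.oy[s] = F.oy[p] + sw * ax + cw * ay;
    int d = C.seg_dof[s];
    F.w[s] = F.w[p] + C.seg_sign[s] * q[d];
    F.wd[s] = F.wd[p] + (qd ? C.seg_sign[s] * qd[d] : 0.0);
  }
}

static inline void world_point(const Core& C, const Frames& F, int s,
                               double lx, double ly, double& px, double& py) {
  double cw = std::cos(F.w[s]), sw = std::sin(F.w[s]);
  px = F.ox[s] + cw * lx - sw * ly;
  py = F.oy[s] + sw * lx + cw * ly;
}

// Fill the 2 x ndof Jacobian of a world point attached to segment s.
static void point_jac(const Core& C, const Frames& F, int s, double px,
                      double py, double* Jx, double* Jy) {
  for (int i = 0; i < C.ndof; ++i) { Jx[i] = 0.0; Jy[i] = 0.0; }
  Jx[0] = 1.0;
  Jy[1] = 1.0;
  for (int a = s; a >= 0; a = C.seg_parent[a]) {
    if (a == 0) {
      Jx[2] += -(py - F.oy[0]);
      Jy[2] += (px - F.ox[0]);
      break;
    }
    int d = C.seg_dof[a];
    double sg = C.seg_sign[a];
    Jx[d] += -sg * (py - F.oy[a]);
    Jy[d] += sg * (px - F.ox[a]);
  }
}

// MTU path length and moment arms r_j = dL/dtheta_j (joint dofs only).
static void muscle_geom(const Core& C, const Frames& F, int m, double& L,
                        double* r /* nj */) {
  L = 0.0;
  for (int j = 0; j < C.nj; ++j) r[j] = 0.0;
  int p0 = C.mus_ptr[m], p1 = C.mus_ptr[m + 1];
  double px[8], py[8];
  double jx[8][16], jy[8][16];  // per point, joint-dof jacobian
  int npt = p1 - p0;
  for (int k = 0; k < npt; ++k) {
    int s = C.mus_seg[p0 + k];
    world_point(C, F, s, C.mus_xy(0, p0 + k), C.mus_xy(1, p0 + k), px[k], py[k]);
    for (int j = 0; j < C.nj; ++j) { jx[k][j] = 0.0; jy[k][j] = 0.0; }
    for (int a = s; a > 0; a = C.seg_parent[a]) {
      int d = C.seg_dof[a] - 3;
      double sg = C.seg_sign[a];
      jx[k][d] += -sg * (py[k] - F.oy[a]);
      jy[k][d] += sg * (px[k] - F.ox[a]);
    }
  }
  for (int k = 0; k + 1 < npt; ++k) {
    double dx = px[k + 1] - px[k], dy = py[k + 1] - py[k];
    double len = std::sqrt(dx * dx + dy * dy);
    if (len < 1e-9) continue;  // transient degenerate geometry: no direction
    L += len;
    double ux = dx / len, uy = dy / len;
    for (int j = 0; j < C.nj; ++j)
      r[j] += ux * (jx[k + 1][j] - jx[k][j]) + uy * (jy[k + 1][j] - jy[k][j]);
  }
}

// [[Rcpp::export]]
List cpp_muscle_geometry(List core, NumericVector q) {
  Core C(core);
  Frames F;
  fk(C, q.begin(), nullptr, F);
  NumericVector L(C.nm);
  NumericMatrix R(C.nm, C.nj);
  std::vector<double> r(C.nj);
  for (int m = 0; m < C.nm; ++m) {
    double Lm;
    muscle_geom(C, F, m, Lm, r.data());
    L[m] = Lm;
    for (int j = 0; j < C.nj; ++j) R(m, j) = r[j];
  }
  return List::create(_["L"] = L, _["R"] = R);
}

// [[Rcpp::export]]
NumericMatrix cpp_points_world(List core, NumericVector q, IntegerVector segs,
                               NumericMatrix local) {
  Core C(core);
  Frames F;
  fk(C, q.begin(), nullptr, F);
  int n = segs.size();
  NumericMatrix out(2, n);
  for (int i = 0; i < n; ++i)
    world_point(C, F, segs[i], local(0, i), local(1, i), out(0, i), out(1, i));
  return out;
}

// [[Rcpp::export]]
List cpp_com(List core, NumericVector q, NumericVector qd) {
  Core C(core);
  Frames F;
  fk(C, q.begin(), qd.begin(), F);
  double M = 0.0, cx = 0.0, cy = 0.0, vx = 0.0, vy = 0.0;
  std::vector<double> Jx(C.ndof), Jy(C.ndof);
  for (int s = 0; s < C.ns; ++s) {
    double px, py;
    world_point(C, F, s, C.com(0, s), C.com(1, s), px, py);
    point_jac(C, F, s, px, py, Jx.data(), Jy.data());
    double vxs = 0.0, vys = 0.0;
    for (int i = 0; i < C.ndof; ++i) {
      vxs += Jx[i] * qd[i];
      vys += Jy[i] * qd[i];
    }
    M += C.mass[s];
    cx += C.mass[s] * px;
    cy += C.mass[s] * py;
    vx += C.mass[s] * vxs;
    vy += C.mass[s] * vys;
  }
  return List::create(_["com"] = NumericVector::create(cx / M, cy / M),
                      _["comv"] = NumericVector::create(vx / M, vy / M),
                      _["mass"] = M);
}

// ---------------------------------------------------------------------------
// Terrain: height and friction as functions of world x.

struct Terr {
  int kind;  // 0 flat, 1 slip transition, 2 uneven
  double mu0, mu1, tx, hx0, hdx;
  NumericVector hgrid;
  explicit Terr(const List& L)
      : hgrid(as<NumericVector>(L["hgrid"])) {
    kind = as<int>(L["kind"]);
    mu0 = as<double>(L["mu0"]);
    mu1 = as<double>(L["mu1"]);
    tx = as<double>(L["transition_x"]);
    hx0 = as<double>(L["hx0"]);
    hdx = as<double>(L["hdx"]);
  }
  double height(double x) const {
    if (kind != 2 || hgrid.size() == 0 || x <= tx) return 0.0;
    double u = (x - hx0) / hdx;
    int i = (int)std::floor(u);
    if (i < 0) return 0.0;
    if (i >= hgrid.size() - 1) return hgrid[hgrid.size() - 1];
    double f = u - i;
    return (1.0 - f) * hgrid[i] + f * hgrid[i + 1];
  }
  double mu(double x) const {
    if (kind == 1 && x >= tx) return mu1;
    return mu0;
  }
};

// Per-sphere contact force at a given kinematic state (no integration).
// Returns nsph x 6: normal N, friction N, contact x, contact y, penetration,
// mu used.
// [[Rcpp::export]]
NumericMatrix cpp_contact(List core, List terrain, NumericVector q,
                          NumericVector qd) {
  Core C(core);
  Terr T(terrain);
  Frames F;
  fk(C, q.begin(), qd.begin(), F);
  NumericMatrix out(C.nsph, 6);
  std::vector<double> Jx(C.ndof), Jy(C.ndof);
  for (int k = 0; k < C.nsph; ++k) {
    int s = C.sph_seg[k];
    double px, py;
    world_point(C, F, s, C.sph_xy(0, k), C.sph_xy(1, k), px, py);
    double cpx = px, cpy = py - C.sph_r[k];
    double h = T.height(cpx);
    double pen = h - cpy;
    double N = 0.0, ft = 0.0, mu = T.mu(cpx);
    if (pen > 0.0) {
      point_jac(C, F, s, cpx, cpy, Jx.data(), Jy.data());
      double vx = 0.0, vy = 0.0;
      for (int i = 0; i < C.ndof; ++i) {
        vx += Jx[i] * qd[i];
        vy += Jy[i] * qd[i];
      }
      N = C.kn * pen * (1.0 + C.cn * std::max(0.0, -vy));
      if (N < 0.0) N = 0.0;
      ft = -mu * N * std::tanh(vx / C.veps);
    }
    out(k, 0) = N;
    out(k, 1) = ft;
    out(k, 2) = cpx;
    out(k, 3) = cpy;
    out(k, 4) = pen;
    out(k, 5) = mu;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Muscle mechanics at a given state: tendon force, moment arms and the
// fiber / tendon / series stiffness decomposition (quasi-static: the
// force-velocity multiplier is taken at the supplied normalized fiber
// velocity and is NOT differentiated).
// [[Rcpp::export]]
List cpp_muscle_mech(List core, NumericVector q, NumericVector act,
                     NumericVector lfib, NumericVector vtilde) {
  Core C(core);
  const double* cc = C.cc.begin();
  Frames F;
  fk(C, q.begin(), nullptr, F);
  NumericVector L(C.nm), Fm(C.nm), KM(C.nm), KT(C.nm), KMTU(C.nm);
  NumericMatrix R(C.nm, C.nj);
  std::vector<double> r(C.nj);
  for (int m = 0; m < C.nm; ++m) {
    double Lm;
    muscle_geom(C, F, m, Lm, r.data());
    L[m] = Lm;
    for (int j = 0; j < C.nj; ++j) R(m, j) = r[j];
    double lf = lfib[m];
    double sina = std::min(0.99, std::sin(C.penn[m]) * C.lopt[m] / std::max(lf, 1e-9));
    double cosa = std::sqrt(1.0 - sina * sina);
    double eps = (Lm - lf * cosa) / C.lslack[m] - 1.0;
    double fT = ten_fl(eps, cc);
    Fm[m] = C.F0[m] * fT;
    KT[m] = C.F0[m] / C.lslack[m] * ten_fl_d(eps, cc);
    double lt = lf / C.lopt[m];
    double fv = fv_curve(vtilde[m], cc);
    KM[m] = C.F0[m] / C.lopt[m] *
            (act[m] * act_fl_d(lt, cc) * fv + pas_fl_d(lt, cc)) * cosa * cosa;
    double den = KM[m] + KT[m];
    KMTU[m] = (std::fabs(den) < 1e-9) ? 0.0 : KM[m] * KT[m] / den;
  }
  return List::create(_["L"] = L, _["R"] = R, _["force"] = Fm, _["KM"] = KM,
                      _["KT"] = KT, _["KMTU"] = KMTU);
}

// Instantaneous analytic joint stiffness (Nm/rad) from simulator muscle
// states, used inside reward evaluation during rollouts. dr/dtheta by central
// difference of the analytic moment arm.
// [[Rcpp::export]]
NumericVector cpp_joint_stiffness_inst(List core, NumericVector q,
                                       NumericVector act, NumericVector lfib) {
  Core C(core);
  const double* cc = C.cc.begin();
  Frames F;
  fk(C, q.begin(), nullptr, F);
  std::vector<double> r0(C.nm * C.nj), Fm(C.nm), KMTU(C.nm), r(C.nj);
  for (int m = 0; m < C.nm; ++m) {
    double Lm;
    muscle_geom(C, F, m, Lm, r.data());
    for (int j = 0; j < C.nj; ++j) r0[m * C.nj + j] = r[j];
    double lf = lfib[m];
    double sina = std::min(0.99, std::sin(C.penn[m]) * C.lopt[m] / std::max(lf, 1e-9));
    double cosa = std::sqrt(1.0 - sina * sina);
    double eps = (Lm - lf * cosa) / C.lslack[m] - 1.0;
    Fm[m] = C.F0[m] * ten_fl(eps, cc);
    double KT = C.F0[m] / C.lslack[m] * ten_fl_d(eps, cc);
    double lt = lf / C.lopt[m];
    double KM = C.F0[m] / C.lopt[m] *
                (act[m] * act_fl_d(lt, cc) + pas_fl_d(lt, cc)) * cosa * cosa;
    double den = KM + KT;
    KMTU[m] = (std::fabs(den) < 1e-9) ? 0.0 : KM * KT / den;
  }
  const double dlt = 1e-5;
  NumericVector K(C.nj);
  std::vector<double> qp(q.begin(), q.end());
  std::vector<double> rp(C.nj), rm(C.nj);
  Frames Fp;
  for (int j = 0; j < C.nj; ++j) {
    double Kj = 0.0;
    qp[3 + j] = q[3 + j] + dlt;
    fk(C, qp.data(), nullptr, Fp);
    std::vector<double> rps(C.nm), rms(C.nm);
    for (int m = 0; m < C.nm; ++m) {
      double Lm;
      muscle_geom(C, Fp, m, Lm, rp.data());
      rps[m] = rp[j];
    }
    qp[3 + j] = q[3 + j] - dlt;
    fk(C, qp.data(), nullptr, Fp);
    for (int m = 0; m < C.nm; ++m) {
      double Lm;
      muscle_geom(C, Fp, m, Lm, rm.data());
      rms[m] = rm[j];
    }
    qp[3 + j] = q[3 + j];
    for (int m = 0; m < C.nm; ++m) {
      double drdth = (rps[m] - rms[m]) / (2.0 * dlt);
      double rj = r0[m * C.nj + j];
      Kj += drdth * Fm[m] + KMTU[m] * rj * rj;
    }
    K[j] = Kj;
  }
  return K;
}

// ---------------------------------------------------------------------------
// Forward dynamics step: nsub physics substeps of size dt.

static void solve_lin(std::vector<double>& A, std::vector<double>& b, int n) {
  // Gaussian elimination with partial pivoting; A is n x n row-major.
  for (int k = 0; k < n; ++k) {
    int piv = k;
    double best = std::fabs(A[k * n + k]);
    for (int i = k + 1; i < n; ++i) {
      double v = std::fabs(A[i * n + k]);
      if (v > best) { best = v; piv = i; }
    }
    if (best < 1e-12) stop("singular mass matrix");
    if (piv != k) {
      for (int j = 0; j < n; ++j) std::swap(A[k * n + j], A[piv * n + j]);
      std::swap(b[k], b[piv]);
    }
    for (int i = k + 1; i < n; ++i) {
      double f = A[i * n + k] / A[k * n + k];
      if (f == 0.0) continue;
      for (int j = k; j < n; ++j) A[i * n + j] -= f * A[k * n + j];
      b[i] -= f * b[k];
    }
  }
  for (int i = n - 1; i >= 0; --i) {
    double s = b[i];
    for (int j = i + 1; j < n; ++j) s -= A[i * n + j] * b[j];
    b[i] = s / A[i * n + i];
  }
}

// [[Rcpp::export]]
List cpp_step(List core, List terrain, NumericVector state, NumericVector u,
              int nsub, double dt) {
  Core C(core);
  Terr T(terrain);
  const double* cc = C.cc.begin();
  int nd = C.ndof, nm = C.nm;
  if ((int)state.size() != 2 * nd + 2 * nm + 1)
    stop("state vector has wrong length");
  std::vector<double> q(state.begin(), state.begin() + nd);
  std::vector<double> qd(state.begin() + nd, state.begin() + 2 * nd);
  std::vector<double> act(state.begin() + 2 * nd, state.begin() + 2 * nd + nm);
  std::vector<double> lf(state.begin() + 2 * nd + nm,
                         state.begin() + 2 * nd + 2 * nm);
  double t = state[2 * nd + 2 * nm];

  Frames F;
  std::vector<double> Jx(nd), Jy(nd), r(C.nj);
  std::vector<double> M(nd * nd), Q(nd);
  std::vector<double> mforce(nm);
  NumericMatrix sph_log(C.nsph, 4);  // N, ft, cpx, cpy (last substep)

  std::vector<int> freeIdx;
  for (int i = 0; i < nd; ++i)
    if (C.dof_free[i]) freeIdx.push_back(i);
  int nf = (int)freeIdx.size();
  std::vector<double> Ared(nf * nf), bred(nf);

  for (int sub = 0; sub < nsub; ++sub) {
    // --- activation dynamics (first order, activation-scaled time constants)
    for (int m = 0; m < nm; ++m) {
      double um = u[m];
      double tau = (um > act[m]) ? C.tact[m] * (0.5 + 1.5 * act[m])
                                 : C.tdeact[m] / (0.5 + 1.5 * act[m]);
      act[m] += dt * (um - act[m]) / tau;
      if (act[m] < 0.0) act[m] = 0.0;
      if (act[m] > 1.0) act[m] = 1.0;
    }

    fk(C, q.data(), qd.data(), F);
    std::fill(Q.begin(), Q.end(), 0.0);
    std::fill(M.begin(), M.end(), 0.0);

    // --- muscles: fiber dynamics + generalized forces
    for (int m = 0; m < nm; ++m) {
      double Lm;
      muscle_geom(C, F, m, Lm, r.data());
      double lfm = lf[m];
      double sina = std::min(0.99, std::sin(C.penn[m]) * C.lopt[m] /
                                       std::max(lfm, 1e-9));
      double cosa = std::sqrt(1.0 - sina * sina);
      double eps = (Lm - lfm * cosa) / C.lslack[m] - 1.0;
      double fT = ten_fl(eps, cc);
      double ltil = lfm / C.lopt[m];
      double flA = act_fl(ltil, cc);
      double fP = pas_fl(ltil, cc);
      // damped fiber equilibrium: solve a*flA*fv(x) + beta*x + fP = fT/cosa
      // for the normalized fiber velocity x (monotone in x; bisection)
      double gt = fT / cosa - fP;
      double aF = act[m] * flA;
      double beta = C.mus_beta;
      double xlo = -1.0, xhi = 2.0;
      double hlo = aF * fv_curve(xlo, cc) + beta * xlo - gt;
      double hhi = aF * fv_curve(xhi, cc) + beta * xhi - gt;
      double x;
      if (hlo >= 0.0) x = xlo;
      else if (hhi <= 0.0) x = xhi;
      else {
        for (int it = 0; it < 40; ++it) {
          x = 0.5 * (xlo + xhi);
          double h = aF * fv_curve(x, cc) + beta * x - gt;
          if (h > 0.0) xhi = x; else xlo = x;
        }
        x = 0.5 * (xlo + xhi);
      }
      double vf = x * C.vmax[m] * C.lopt[m];
      lf[m] = lfm + vf * dt;
      double lo = 0.2 * C.lopt[m], hi = 1.8 * C.lopt[m];
      if (lf[m] < lo) lf[m] = lo;
      if (lf[m] > hi) lf[m] = hi;
      double Fmus = C.F0[m] * fT;
      mforce[m] = Fmus;
      for (int j = 0; j < C.nj; ++j) Q[3 + j] -= Fmus * r[j];
    }

    // --- joint limits and viscous joint damping
    for (int j = 0; j < C.nj; ++j) {
      int d = 3 + j;
      double tau = -C.joint_damp * qd[d];
      if (q[d] > C.jlim_hi[j])
        tau += -C.jlim_k * (q[d] - C.jlim_hi[j]) - C.jlim_c * qd[d];
      else if (q[d] < C.jlim_lo[j])
        tau += C.jlim_k * (C.jlim_lo[j] - q[d]) - C.jlim_c * qd[d];
      Q[d] += tau;
    }

    // --- contact
    for (int k = 0; k < C.nsph; ++k) {
      int s = C.sph_seg[k];
      double px, py;
      world_point(C, F, s, C.sph_xy(0, k), C.sph_xy(1, k), px, py);
      double cpx = px, cpy = py - C.sph_r[k];
      double h = T.height(cpx);
      double pen = h - cpy;
      double N = 0.0, ft = 0.0;
      if (pen > 0.0) {
        point_jac(C, F, s, cpx, cpy, Jx.data(), Jy.data());
        double vx = 0.0, vy = 0.0;
        for (int i = 0; i < nd; ++i) {
          vx += Jx[i] * qd[i];
          vy += Jy[i] * qd[i];
        }
        N = C.kn * pen * (1.0 + C.cn * std::max(0.0, -vy));
        if (N < 0.0) N = 0.0;
        double mu = T.mu(cpx);
        ft = -mu * N * std::tanh(vx / C.veps);
        for (int i = 0; i < nd; ++i) Q[i] += Jx[i] * ft + Jy[i] * N;
      }
      if (sub == nsub - 1) {
        sph_log(k, 0) = N;
        sph_log(k, 1) = ft;
        sph_log(k, 2) = cpx;
        sph_log(k, 3) = cpy;
      }
    }

    // --- mass matrix, gravity and velocity-product terms
    std::vector<double> ao_x(C.ns, 0.0), ao_y(C.ns, 0.0);
    for (int s = 1; s < C.ns; ++s) {
      int p = C.seg_parent[s];
      double wp2 = F.wd[p] * F.wd[p];
      ao_x[s] = ao_x[p] - wp2 * (F.ox[s] - F.ox[p]);
      ao_y[s] = ao_y[p] - wp2 * (F.oy[s] - F.oy[p]);
    }
    for (int s = 0; s < C.ns; ++s) {
      double cx, cy;
      world_point(C, F, s, C.com(0, s), C.com(1, s), cx, cy);
      point_jac(C, F, s, cx, cy, Jx.data(), Jy.data());
      double ms = C.mass[s];
      double w2 = F.wd[s] * F.wd[s];
      double abx = ao_x[s] - w2 * (cx - F.ox[s]);
      double aby = ao_y[s] - w2 * (cy - F.oy[s]);
      // angular jacobian row
      std::vector<double> jw(nd, 0.0);
      for (int a = s; a >= 0; a = C.seg_parent[a]) {
        if (a == 0) { jw[2] += 1.0; break; }
        jw[C.seg_dof[a]] += C.seg_sign[a];
      }
      for (int i = 0; i < nd; ++i) {
        double Jxi = Jx[i], Jyi = Jy[i], jwi = jw[i];
        if (Jxi == 0.0 && Jyi == 0.0 && jwi == 0.0) continue;
        Q[i] += ms * (Jyi * (-C.grav)) - ms * (Jxi * abx + Jyi * aby);
        for (int jj = i; jj < nd; ++jj) {
          double v = ms * (Jxi * Jx[jj] + Jyi * Jy[jj]) +
                     C.inertia[s] * jwi * jw[jj];
          M[i * nd + jj] += v;
        }
      }
    }
    for (int i = 0; i < nd; ++i)
      for (int jj = 0; jj < i; ++jj) M[i * nd + jj] = M[jj * nd + i];

    // --- reduced solve over free dofs, semi-implicit Euler
    for (int a = 0; a < nf; ++a) {
      bred[a] = Q[freeIdx[a]];
      for (int b = 0; b < nf; ++b) Ared[a * nf + b] = M[freeIdx[a] * nd + freeIdx[b]];
    }
    solve_lin(Ared, bred, nf);
    for (int a = 0; a < nf; ++a) {
      int i = freeIdx[a];
      qd[i] += dt * bred[a];
    }
    for (int i = 0; i < nd; ++i) q[i] += dt * qd[i];
    t += dt;

    for (int i = 0; i < nd; ++i)
      if (!std::isfinite(q[i]) || !std::isfinite(qd[i]))
        stop("non-finite state at dof %d, t = %f", i, t);
  }

  // --- outputs from final state
  fk(C, q.data(), qd.data(), F);
  NumericVector grf_r(2), grf_l(2), cop(2);  // cop: per-foot x (0 if none)
  double wsum_r = 0.0, wsum_l = 0.0, copx_r = 0.0, copx_l = 0.0;
  double heel_r = 0.0, heel_l = 0.0;
  for (int k = 0; k < C.nsph; ++k) {
    double N = sph_log(k, 0), ft = sph_log(k, 1), cpx = sph_log(k, 2);
    if (C.sph_foot[k] == 0) {
      grf_r[0] += ft; grf_r[1] += N; wsum_r += N; copx_r += N * cpx;
      if (C.sph_heel[k]) heel_r += N;
    } else {
      grf_l[0] += ft; grf_l[1] += N; wsum_l += N; copx_l += N * cpx;
      if (C.sph_heel[k]) heel_l += N;
    }
  }
  cop[0] = wsum_r > 0 ? copx_r / wsum_r : 0.0;
  cop[1] = wsum_l > 0 ? copx_l / wsum_l : 0.0;

  double Mtot = 0.0, cx = 0.0, cy = 0.0, cvx = 0.0, cvy = 0.0;
  for (int s = 0; s < C.ns; ++s) {
    double px, py;
    world_point(C, F, s, C.com(0, s), C.com(1, s), px, py);
    point_jac(C, F, s, px, py, Jx.data(), Jy.data());
    double vxs = 0.0, vys = 0.0;
    for (int i = 0; i < nd; ++i) {
      vxs += Jx[i] * qd[i];
      vys += Jy[i] * qd[i];
    }
    Mtot += C.mass[s];
    cx += C.mass[s] * px; cy += C.mass[s] * py;
    cvx += C.mass[s] * vxs; cvy += C.mass[s] * vys;
  }
  NumericMatrix eff(2, C.neff);
  for (int e = 0; e < C.neff; ++e)
    world_point(C, F, C.eff_seg[e], C.eff_xy(0, e), C.eff_xy(1, e), eff(0, e),
                eff(1, e));

  NumericVector out_state(2 * nd + 2 * nm + 1);
  for (int i = 0; i < nd; ++i) { out_state[i] = q[i]; out_state[nd + i] = qd[i]; }
  for (int m = 0; m < nm; ++m) {
    out_state[2 * nd + m] = act[m];
    out_state[2 * nd + nm + m] = lf[m];
  }
  out_state[2 * nd + 2 * nm] = t;

  return List::create(
      _["state"] = out_state, _["grf_r"] = grf_r, _["grf_l"] = grf_l,
      _["cop_x"] = cop, _["heel_fz"] = NumericVector::create(heel_r, heel_l),
      _["com"] = NumericVector::create(cx / Mtot, cy / Mtot),
      _["comv"] = NumericVector::create(cvx / Mtot, cvy / Mtot),
      _["eff"] = eff, _["mtu_force"] = NumericVector(mforce.begin(), mforce.end()),
      _["spheres"] = sph_log);
}
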