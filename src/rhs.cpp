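// Compiled right-hand side of the stance-phase equations of motion.
//
// The articulated-foot dynamics (forward kinematics, muscle path forces,
// sphere-plane contact, gravity, passive joint torques, velocity-product
// bias by recursive Newton-Euler, and the joint-space mass matrix) are
// evaluated here for speed; the R implementations of the same quantities
// remain the reference and are cross-checked in the test suite.  Plane
// pose and path tensions are supplied as dense time grids prepared in R
// and interpolated linearly (the grids are fine enough that the
// interpolation error is far below integrator tolerance).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double a, double b, double c) : x(a), y(b), z(c) {}
};

inline Vec3 operator+(const Vec3& a, const Vec3& b) {
  return Vec3(a.x + b.x, a.y + b.y, a.z + b.z);
}
inline Vec3 operator-(const Vec3& a, const Vec3& b) {
  return Vec3(a.x - b.x, a.y - b.y, a.z - b.z);
}
inline Vec3 operator*(double s, const Vec3& a) {
  return Vec3(s * a.x, s * a.y, s * a.z);
}
inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
              a.x * b.y - a.y * b.x);
}
inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }

struct Mat3 {
  double m[9];  // column-major
  Mat3() { for (int i = 0; i < 9; ++i) m[i] = 0; }
  static Mat3 identity() {
    Mat3 r; r.m[0] = r.m[4] = r.m[8] = 1; return r;
  }
  Vec3 col(int j) const { return Vec3(m[3 * j], m[3 * j + 1], m[3 * j + 2]); }
};

inline Vec3 mul(const Mat3& R, const Vec3& v) {
  return Vec3(R.m[0] * v.x + R.m[3] * v.y + R.m[6] * v.z,
              R.m[1] * v.x + R.m[4] * v.y + R.m[7] * v.z,
              R.m[2] * v.x + R.m[5] * v.y + R.m[8] * v.z);
}
inline Mat3 mul(const Mat3& A, const Mat3& B) {
  Mat3 C;
  for (int j = 0; j < 3; ++j)
    for (int i = 0; i < 3; ++i) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += A.m[i + 3 * k] * B.m[k + 3 * j];
      C.m[i + 3 * j] = s;
    }
  return C;
}
inline Mat3 rot_axis(const Vec3& a, double th) {
  double c = std::cos(th), s = std::sin(th), v = 1 - c;
  Mat3 R;
  R.m[0] = c + a.x * a.x * v;
  R.m[1] = a.x * a.y * v + a.z * s;
  R.m[2] = a.x * a.z * v - a.y * s;
  R.m[3] = a.x * a.y * v - a.z * s;
  R.m[4] = c + a.y * a.y * v;
  R.m[5] = a.y * a.z * v + a.x * s;
  R.m[6] = a.x * a.z * v + a.y * s;
  R.m[7] = a.y * a.z * v - a.x * s;
  R.m[8] = c + a.z * a.z * v;
  return R;
}
// R * I * R^T with I given column-major
inline Mat3 rotate_inertia(const Mat3& R, const double* I) {
  Mat3 Im; for (int i = 0; i < 9; ++i) Im.m[i] = I[i];
  Mat3 RI = mul(R, Im);
  Mat3 out;
  for (int j = 0; j < 3; ++j)
    for (int i = 0; i < 3; ++i) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += RI.m[i + 3 * k] * R.m[j + 3 * k];
      out.m[i + 3 * j] = s;
    }
  return out;
}

struct Path {
  std::vector<int> body;
  std::vector<Vec3> pts;
  double amp;
};

struct Ctx {
  int nq;
  std::vector<int> parent;          // 0 = fixed tibia
  std::vector<Vec3> jo, axis, com;
  std::vector<double> stiffness, damping, neutral, range_lo, range_hi, mass;
  std::vector<double> inertia;      // 9 per body, column-major
  double stop_k;
  // spheres
  std::vector<int> sp_body;
  std::vector<Vec3> sp_center;
  std::vector<double> sp_radius, sp_k;
  double cp, cd, cfv;
  double gravity;
  std::vector<Path> paths;
  // time grids
  std::vector<double> tgrid;
  std::vector<double> plane_R;      // 9 x m
  std::vector<double> plane_p, plane_v, plane_w;  // 3 x m
  std::vector<double> tension;      // np x m
  // scratch
  std::vector<Mat3> R;
  std::vector<Vec3> O, waxes, cw;
  std::vector<Mat3> Iw;
};

inline void accum_point(const Ctx& c, const std::vector<Vec3>& O,
                        const std::vector<Vec3>& ax, int b, const Vec3& P,
                        const Vec3& F, double* tau) {
  int j = b;
  while (j != 0) {
    Vec3 r = P - O[j - 1];
    tau[j - 1] += dot(cross(ax[j - 1], r), F);
    j = c.parent[j - 1];
  }
}

void solve5(double* A, double* b, int n) {  // in-place Gauss, partial pivot
  for (int k = 0; k < n; ++k) {
    int piv = k;
    double mx = std::fabs(A[k + n * k]);
    for (int i = k + 1; i < n; ++i)
      if (std::fabs(A[i + n * k]) > mx) { mx = std::fabs(A[i + n * k]); piv = i; }
    if (mx < 1e-300) Rcpp::stop("singular mass matrix");
    if (piv != k) {
      for (int j = 0; j < n; ++j) std::swap(A[k + n * j], A[piv + n * j]);
      std::swap(b[k], b[piv]);
    }
    for (int i = k + 1; i < n; ++i) {
      double f = A[i + n * k] / A[k + n * k];
      for (int j = k; j < n; ++j) A[i + n * j] -= f * A[k + n * j];
      b[i] -= f * b[k];
    }
  }
  for (int k = n - 1; k >= 0; --k) {
    double s = b[k];
    for (int j = k + 1; j < n; ++j) s -= A[k + n * j] * b[j];
    b[k] = s / A[k + n * k];
  }
}

}  // namespace

// [[Rcpp::export(name = ".rhs_context")]]
SEXP rhs_context(List model, List grids) {
  Ctx* c = new Ctx();
  c->nq = as<int>(model["nq"]);
  IntegerVector par = model["parent"];
  NumericMatrix jo = model["jo"], axis = model["axis"], com = model["com"];
  NumericVector stiff = model["stiffness"], damp = model["damping"],
                neutral = model["neutral"], mass = model["mass"];
  NumericMatrix range = model["range"];
  NumericVector inert = model["inertia"];
  for (int k = 0; k < c->nq; ++k) {
    c->parent.push_back(par[k]);
    c->jo.push_back(Vec3(jo(0, k), jo(1, k), jo(2, k)));
    c->axis.push_back(Vec3(axis(0, k), axis(1, k), axis(2, k)));
    c->com.push_back(Vec3(com(0, k), com(1, k), com(2, k)));
    c->stiffness.push_back(stiff[k]);
    c->damping.push_back(damp[k]);
    c->neutral.push_back(neutral[k]);
    c->range_lo.push_back(range(0, k));
    c->range_hi.push_back(range(1, k));
    c->mass.push_back(mass[k]);
    for (int i = 0; i < 9; ++i) c->inertia.push_back(inert[9 * k + i]);
  }
  c->stop_k = as<double>(model["stop_k"]);
  IntegerVector spb = model["sphere_body"];
  NumericMatrix spc = model["sphere_center"];
  NumericVector spr = model["sphere_radius"];
  NumericVector spk = model["sphere_k"];
  for (int i = 0; i < spb.size(); ++i) {
    c->sp_body.push_back(spb[i]);
    c->sp_center.push_back(Vec3(spc(0, i), spc(1, i), spc(2, i)));
    c->sp_radius.push_back(spr[i]);
    c->sp_k.push_back(spk[i]);
  }
  List ct = model["contact"];
  c->cp = as<double>(ct["exponent"]);
  c->cd = as<double>(ct["dissipation"]);
  c->cfv = as<double>(ct["f_v"]);
  c->gravity = as<double>(model["gravity"]);
  List paths = model["paths"];
  for (int p = 0; p < paths.size(); ++p) {
    List pl = paths[p];
    Path pa;
    IntegerVector pb = pl["body"];
    NumericMatrix pp = pl["points"];
    for (int i = 0; i < pb.size(); ++i) {
      pa.body.push_back(pb[i]);
      pa.pts.push_back(Vec3(pp(0, i), pp(1, i), pp(2, i)));
    }
    pa.amp = as<double>(pl["amp"]);
    c->paths.push_back(pa);
  }
  NumericVector tg = grids["t"];
  NumericMatrix pR = grids["R"], ppos = grids["p"], pv = grids["v"],
                pw = grids["w"], tens = grids["tension"];
  int m = tg.size();
  for (int i = 0; i < m; ++i) c->tgrid.push_back(tg[i]);
  c->plane_R.assign(pR.begin(), pR.end());
  c->plane_p.assign(ppos.begin(), ppos.end());
  c->plane_v.assign(pv.begin(), pv.end());
  c->plane_w.assign(pw.begin(), pw.end());
  c->tension.assign(tens.begin(), tens.end());
  c->R.resize(c->nq);
  c->O.resize(c->nq);
  c->waxes.resize(c->nq);
  c->cw.resize(c->nq);
  c->Iw.resize(c->nq);
  XPtr<Ctx> xp(c, true);
  return xp;
}

// [[Rcpp::export(name = ".rhs_eval")]]
NumericVector rhs_eval(SEXP ctx, double t, NumericVector y) {
  XPtr<Ctx> xp(ctx);
  Ctx& c = *xp;
  const int nq = c.nq;
  const int m = (int)c.tgrid.size();
  const int np = (int)c.paths.size();

  // clamp and locate on the time grid
  double t0 = c.tgrid.front(), t1 = c.tgrid.back();
  double tc = t < t0 ? t0 : (t > t1 ? t1 : t);
  double u = (tc - t0) / (t1 - t0) * (m - 1);
  int i0 = (int)u; if (i0 > m - 2) i0 = m - 2;
  double w1 = u - i0, w0 = 1 - w1;

  Mat3 plR;
  for (int i = 0; i < 9; ++i)
    plR.m[i] = w0 * c.plane_R[9 * i0 + i] + w1 * c.plane_R[9 * (i0 + 1) + i];
  Vec3 plp(w0 * c.plane_p[3 * i0] + w1 * c.plane_p[3 * (i0 + 1)],
           w0 * c.plane_p[3 * i0 + 1] + w1 * c.plane_p[3 * (i0 + 1) + 1],
           w0 * c.plane_p[3 * i0 + 2] + w1 * c.plane_p[3 * (i0 + 1) + 2]);
  Vec3 plv(w0 * c.plane_v[3 * i0] + w1 * c.plane_v[3 * (i0 + 1)],
           w0 * c.plane_v[3 * i0 + 1] + w1 * c.plane_v[3 * (i0 + 1) + 1],
           w0 * c.plane_v[3 * i0 + 2] + w1 * c.plane_v[3 * (i0 + 1) + 2]);
  Vec3 plw(w0 * c.plane_w[3 * i0] + w1 * c.plane_w[3 * (i0 + 1)],
           w0 * c.plane_w[3 * i0 + 1] + w1 * c.plane_w[3 * (i0 + 1) + 1],
           w0 * c.plane_w[3 * i0 + 2] + w1 * c.plane_w[3 * (i0 + 1) + 2]);
  Vec3 n = plR.col(1);
  double nn = norm(n);
  n = (1.0 / nn) * n;

  std::vector<double> tens(np);
  for (int p = 0; p < np; ++p)
    tens[p] = w0 * c.tension[np * i0 + p] + w1 * c.tension[np * (i0 + 1) + p];

  const double* q = REAL(y);
  const double* qd = q + nq;

  // forward kinematics
  for (int k = 0; k < nq; ++k) {
    int p = c.parent[k];
    Mat3 Rj = rot_axis(c.axis[k], q[k]);
    if (p == 0) {
      c.R[k] = Rj;
      c.O[k] = c.jo[k];
      c.waxes[k] = c.axis[k];
    } else {
      c.R[k] = mul(c.R[p - 1], Rj);
      c.O[k] = c.O[p - 1] + mul(c.R[p - 1], c.jo[k] - c.jo[p - 1]);
      c.waxes[k] = mul(c.R[p - 1], c.axis[k]);
    }
    c.cw[k] = c.O[k] + mul(c.R[k], c.com[k] - c.jo[k]);
    c.Iw[k] = rotate_inertia(c.R[k], &c.inertia[9 * k]);
  }

  std::vector<double> tau(nq, 0.0);

  // muscle path forces
  for (int p = 0; p < np; ++p) {
    double T = tens[p] * c.paths[p].amp;
    if (T <= 0) continue;
    const Path& pa = c.paths[p];
    int K = (int)pa.body.size();
    std::vector<Vec3> w(K);
    for (int i = 0; i < K; ++i) {
      int b = pa.body[i];
      w[i] = (b == 0) ? pa.pts[i]
                      : c.O[b - 1] + mul(c.R[b - 1], pa.pts[i] - c.jo[b - 1]);
    }
    for (int i = 0; i + 1 < K; ++i) {
      int b1 = pa.body[i], b2 = pa.body[i + 1];
      if (b1 == 0 && b2 == 0) continue;
      Vec3 d = w[i + 1] - w[i];
      double L = norm(d);
      Vec3 uv = (1.0 / L) * d;
      if (b1 != 0) accum_point(c, c.O, c.waxes, b1, w[i], T * uv, tau.data());
      if (b2 != 0) accum_point(c, c.O, c.waxes, b2, w[i + 1], (-T) * uv,
                               tau.data());
    }
  }

  // sphere-plane contact
  for (size_t i = 0; i < c.sp_body.size(); ++i) {
    int b = c.sp_body[i];
    Vec3 cwp = c.O[b - 1] + mul(c.R[b - 1], c.sp_center[i] - c.jo[b - 1]);
    double d = c.sp_radius[i] - dot(n, cwp - plp);
    if (d <= 0) continue;
    Vec3 cp = cwp - c.sp_radius[i] * n;
    Vec3 vf(0, 0, 0);
    int j = b;
    while (j != 0) {
      Vec3 r = cp - c.O[j - 1];
      vf = vf + qd[j - 1] * cross(c.waxes[j - 1], r);
      j = c.parent[j - 1];
    }
    Vec3 rp = cp - plp;
    Vec3 vp = plv + cross(plw, rp);
    Vec3 vrel = vf - vp;
    double ddot = -(dot(cross(plw, n), cwp - plp) + dot(n, vf - plv));
    double fn = c.sp_k[i] * std::pow(d, c.cp) * (1 + c.cd * ddot);
    if (fn < 0) fn = 0;
    if (fn == 0) continue;
    Vec3 vs = vrel - dot(n, vrel) * n;
    Vec3 F = fn * n + (-fn * c.cfv) * vs;
    accum_point(c, c.O, c.waxes, b, cp, F, tau.data());
  }

  // gravity + passive joint torques
  Vec3 g(0, -c.gravity, 0);
  for (int k = 0; k < nq; ++k)
    accum_point(c, c.O, c.waxes, k + 1, c.cw[k], c.mass[k] * g, tau.data());
  for (int k = 0; k < nq; ++k) {
    tau[k] += -c.stiffness[k] * (q[k] - c.neutral[k]) - c.damping[k] * qd[k];
    if (q[k] > c.range_hi[k]) tau[k] -= c.stop_k * (q[k] - c.range_hi[k]);
    if (q[k] < c.range_lo[k]) tau[k] -= c.stop_k * (q[k] - c.range_lo[k]);
  }

  // velocity-product bias: RNE with qddot = 0, no gravity
  std::vector<Vec3> omega(nq), alpha(nq), aO(nq), acom(nq);
  for (int k = 0; k < nq; ++k) {
    int p = c.parent[k];
    Vec3 wp(0, 0, 0), ap(0, 0, 0), aOp(0, 0, 0), dO(0, 0, 0);
    if (p != 0) {
      wp = omega[p - 1]; ap = alpha[p - 1]; aOp = aO[p - 1];
      dO = c.O[k] - c.O[p - 1];
    }
    omega[k] = wp + qd[k] * c.waxes[k];
    alpha[k] = ap + qd[k] * cross(wp, c.waxes[k]);
    aO[k] = aOp + cross(ap, dO) + cross(wp, cross(wp, dO));
    Vec3 rc = c.cw[k] - c.O[k];
    acom[k] = aO[k] + cross(alpha[k], rc) + cross(omega[k], cross(omega[k], rc));
  }
  std::vector<Vec3> Fb(nq, Vec3()), Nb(nq, Vec3());
  std::vector<double> bias(nq, 0.0);
  for (int k = nq - 1; k >= 0; --k) {
    Vec3 fk = c.mass[k] * acom[k];
    Vec3 nk = mul(c.Iw[k], alpha[k]) + cross(omega[k], mul(c.Iw[k], omega[k])) +
              cross(c.cw[k] - c.O[k], fk);
    Fb[k] = Fb[k] + fk;
    Nb[k] = Nb[k] + nk;
    bias[k] = dot(c.waxes[k], Nb[k]);
    int p = c.parent[k];
    if (p != 0) {
      Fb[p - 1] = Fb[p - 1] + Fb[k];
      Nb[p - 1] = Nb[p - 1] + Nb[k] + cross(c.O[k] - c.O[p - 1], Fb[k]);
    }
  }

  // mass matrix via centre-of-mass Jacobians
  std::vector<double> M(nq * nq, 0.0);
  for (int k = 0; k < nq; ++k) {
    Vec3 Jv[8], Jw[8];
    std::vector<int> chain;
    int j = k + 1;
    while (j != 0) { chain.push_back(j - 1); j = c.parent[j - 1]; }
    for (size_t a = 0; a < chain.size(); ++a) {
      int ja = chain[a];
      Jv[a] = cross(c.waxes[ja], c.cw[k] - c.O[ja]);
      Jw[a] = c.waxes[ja];
    }
    for (size_t a = 0; a < chain.size(); ++a)
      for (size_t b2 = 0; b2 < chain.size(); ++b2) {
        double val = c.mass[k] * dot(Jv[a], Jv[b2]) +
                     dot(Jw[a], mul(c.Iw[k], Jw[b2]));
        M[chain[a] + nq * chain[b2]] += val;
      }
  }

  std::vector<double> rhs(nq);
  for (int k = 0; k < nq; ++k) rhs[k] = tau[k] - bias[k];
  solve5(M.data(), rhs.data(), nq);

  NumericVector out(2 * nq);
  for (int k = 0; k < nq; ++k) { out[k] = qd[k]; out[nq + k] = rhs[k]; }
  return out;
}
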